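# RNG hygiene: generators set their own seed without clobbering the caller's
# stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# label 4-connected components of a logical matrix; returns integer matrix
# (0 = background). Flood fill with an explicit stack, vectorised per front.
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  nextlab <- 0L
  todo <- which(mask & lab == 0L)
  while (length(todo)) {
    nextlab <- nextlab + 1L
    front <- todo[1]
    while (length(front)) {
      front <- front[mask[front] & lab[front] == 0L]
      if (!length(front)) break
      lab[front] <- nextlab
      r <- (front - 1L) %% nr + 1L
      cl <- (front - 1L) %/% nr + 1L
      nb <- c(front[r > 1L] - 1L, front[r < nr] + 1L,
              front[cl > 1L] - nr, front[cl < nc] + nr)
      front <- unique(nb)
    }
    todo <- which(mask & lab == 0L)
  }
  lab
}
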