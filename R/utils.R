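AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# run expr with a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Hamming distance between two equal-length strings
#'
#' @param a,b character scalars of equal length.
#' @return Integer number of mismatching positions.
#' @export
hamming <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  if (length(va) != length(vb)) stop("hamming(): unequal lengths")
  sum(va != vb)
}

check_alphabet <- function(seq, moltype, id = "sequence") {
  chars <- unique(strsplit(seq, "")[[1]])
  ok <- switch(moltype,
    protein = c(AA20, "X"),
    dna = c("A", "C", "G", "T", "N"))
  bad <- setdiff(chars, ok)
  if (length(bad))
    stop(sprintf("%s: invalid %s character(s): %s", id, moltype,
                 paste(bad, collapse = ", ")))
  invisible(TRUE)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
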