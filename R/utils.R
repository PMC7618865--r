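#' @keywords internal
"_PACKAGE"

#' @importFrom stats ecdf rnorm runif sd setNames
#' @importFrom utils read.delim write.table
NULL

# Run expr with a temporary RNG state seeded from `seed`; the caller's
# .Random.seed is restored afterwards so generators are pure in (args, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Collapse a sorted set of residue numbers into maximal contiguous runs.
segments_from_residues <- function(residues) {
  residues <- sort(unique(as.integer(residues)))
  if (length(residues) == 0L)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  breaks <- which(diff(residues) != 1L)
  starts <- residues[c(1L, breaks + 1L)]
  ends <- residues[c(breaks, length(residues))]
  cbind(start = starts, end = ends)
}

residues_from_segments <- function(segments) {
  if (nrow(segments) == 0L) return(integer(0))
  sort(unique(unlist(lapply(seq_len(nrow(segments)), function(i)
    seq.int(segments[i, 1L], segments[i, 2L])))))
}

# Deterministic TSV writer: fixed column order, no quoting, "." decimal.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
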