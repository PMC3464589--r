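# Internal helpers shared across modules.

RNA_BASES <- c("A", "C", "G", "U")

# Split a sequence (character scalar or Biostrings XString) into an
# uppercase RNA character vector; DNA T is mapped to U.
.asRnaChars <- function(seq) {
  s <- toupper(as.character(seq))
  v <- strsplit(chartr("T", "U", s), "", fixed = TRUE)[[1]]
  bad <- !(v %in% RNA_BASES)
  if (any(bad))
    stop("non-nucleotide symbols in sequence: ",
         paste(unique(v[bad]), collapse = ", "))
  v
}

.collapseChars <- function(v) paste(v, collapse = "")

.revCompChars <- function(v) {
  rev(strsplit(chartr("ACGU", "UGCA", paste(v, collapse = "")), "",
               fixed = TRUE)[[1]])
}

.gcFrac <- function(v) mean(v %in% c("G", "C"))

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library code does not perturb user RNG.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

# Overlap width of [s1,e1) with [s2,e2) (0-based half-open).
.overlapWidth <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

.checkInterval <- function(start, end, what = "interval") {
  if (any(start < 0L) || any(end <= start))
    stop("malformed ", what, ": need 0 <= start < end")
  invisible(TRUE)
}
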