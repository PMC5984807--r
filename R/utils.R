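#' @import data.table
#' @importFrom stats coef lm predict quantile rbeta rbinom rgeom rlnorm rnorm runif wilcox.test cor cor.test complete.cases setNames
#' @importFrom utils read.delim write.table head tail
NULL

# Condition constructor: all package errors carry a subclass so callers and
# tests can branch on the failure mode rather than on message text.
stop_mpsa <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("mpsa_", class), "mpsa_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

DNA_BASES <- c("A", "C", "G", "T")

is_dna <- function(x) {
  nzchar(x) & !grepl("[^ACGT]", x)
}

assert_dna <- function(x, what = "sequence") {
  bad <- which(!is_dna(x))
  if (length(bad)) {
    stop_mpsa("invalid_dna", "%s is not plain A/C/G/T DNA (first offender: %s)",
              what, x[bad[1]])
  }
  invisible(x)
}

#' Reverse complement of DNA strings
#'
#' Thin vectorized wrapper over [Biostrings::reverseComplement()].
#'
#' @param x character vector of A/C/G/T sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  if (length(x) <= 16L) {
    # base-R path: Biostrings object construction dominates for few strings
    comp <- chartr("ACGTacgt", "TGCAtgca", x)
    return(vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
                  USE.NAMES = FALSE))
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between each element of x and a single reference string s.
# All elements must have nchar == nchar(s). Byte-level, vectorized.
hamming_to <- function(x, s) {
  w <- nchar(s)
  if (!length(x)) return(integer(0))
  if (any(nchar(x) != w)) stop_mpsa("length_mismatch", "strings differ in width")
  m <- matrix(as.integer(charToRaw(paste(x, collapse = ""))), nrow = w)
  colSums(m != as.integer(charToRaw(s)))
}

# Pairwise Hamming distance between two equal-width string vectors.
hamming_pair <- function(x, y) {
  if (!length(x)) return(integer(0))
  w <- nchar(x[1])
  if (any(nchar(x) != w) || any(nchar(y) != w)) {
    stop_mpsa("length_mismatch", "strings differ in width")
  }
  mx <- matrix(as.integer(charToRaw(paste(x, collapse = ""))), nrow = w)
  my <- matrix(as.integer(charToRaw(paste(y, collapse = ""))), nrow = w)
  colSums(mx != my)
}

# Random DNA strings, uses the current RNG state.
random_dna <- function(n, len) {
  if (n == 0) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = len)
  apply(m, 2, paste, collapse = "")
}

# Derive a reproducible substream seed (< 2^31) from a master seed and a
# stream label, so independent stages can be re-run in isolation.
derive_seed <- function(seed, stream) {
  h <- 0
  for (b in utf8ToInt(stream)) h <- (h * 131 + b) %% 1000003L
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647) + 1L
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Read / write tab-separated tables
#'
#' All tabular interchange in the package is TSV with a header row.
#'
#' @param path file path.
#' @param x data.frame to write.
#' @return `read_tsv_file` returns a data.frame.
#' @export
read_tsv_file <- function(path) {
  if (!file.exists(path)) stop_mpsa("missing_file", "file not found: %s", path)
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' @rdname read_tsv_file
#' @export
write_tsv_file <- function(x, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  write.table(x, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

# Apply i.i.d. substitution errors to a character vector of DNA sequences.
mutate_seqs <- function(x, rate) {
  if (rate <= 0 || !length(x)) return(x)
  n_err <- rbinom(length(x), nchar(x), rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    pos <- sample.int(nchar(x[i]), n_err[i])
    ch <- strsplit(x[i], "", fixed = TRUE)[[1]]
    for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
    x[i] <- paste(ch, collapse = "")
  }
  x
}

# Integer (0-based) to fixed-width base-4 DNA word.
int_to_dna <- function(i, width) {
  out <- matrix("A", nrow = width, ncol = length(i))
  v <- i
  for (d in width:1) {
    out[d, ] <- DNA_BASES[(v %% 4) + 1]
    v <- v %/% 4
  }
  apply(out, 2, paste, collapse = "")
}
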