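# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded operations (subsampling, simulation) do not perturb the global
#' random stream.
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Standard genetic code, frame 1. Out-of-frame junctions translate to "".
.codon_table <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L", CTA = "L",
  CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M", GTT = "V", GTC = "V",
  GTA = "V", GTG = "V", TCT = "S", TCC = "S", TCA = "S", TCG = "S", CCT = "P",
  CCC = "P", CCA = "P", CCG = "P", ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*",
  TAG = "*", CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E", TGT = "C",
  TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R", GGT = "G", GGC = "G", GGA = "G",
  GGG = "G"
)

#' Translate a CDR3 nucleotide string (frame 1)
#'
#' Returns "" when the sequence length is not a multiple of three
#' (untranslatable junction); unknown codons become "X".
#' @noRd
translate_nt <- function(nt) {
  vapply(nt, function(s) {
    n <- nchar(s)
    if (n == 0L || n %% 3L != 0L) return("")
    codons <- substring(s, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
    aa <- .codon_table[codons]
    aa[is.na(aa)] <- "X"
    paste0(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Check that a numeric vector is a probability vector
#' @noRd
check_prob_vector <- function(p, what = "p", tol = 1e-9, positive = TRUE) {
  if (!is.numeric(p) || length(p) == 0L) {
    stop(sprintf("'%s' must be a non-empty numeric vector", what), call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p < 0)) {
    stop(sprintf("'%s' must contain finite non-negative entries", what),
         call. = FALSE)
  }
  if (positive && any(p <= 0)) {
    stop(sprintf("'%s' must contain strictly positive entries", what),
         call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("'%s' must sum to 1 (got %.12g)", what, sum(p)), call. = FALSE)
  }
  invisible(p)
}

#' @noRd
is_scalar_int <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}

#' Write a data.frame as TSV with full numeric precision
#' @noRd
write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  out <- df
  for (j in which(num)) {
    out[[j]] <- vapply(df[[j]], function(v) {
      if (is.na(v)) "NA" else format(v, digits = 17, scientific = FALSE)
    }, character(1))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @noRd
read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
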