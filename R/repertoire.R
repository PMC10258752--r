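#' Construct a repertoire object
#'
#' A repertoire is the set of unique clonotypes observed for one subject at
#' one locus. Following common AIRR-seq practice, a clonotype is defined by
#' its unique CDR3 nucleotide sequence; reads sharing a CDR3 nucleotide
#' sequence belong to the same clone.
#'
#' @param clonotypes data.frame with columns `cdr3_nt`, `cdr3_aa`, `v_gene`,
#'   `j_gene`, `read_count`, `productive`, `v_identity_pct` and optionally
#'   `pgen`. One row per unique CDR3 nucleotide sequence.
#' @param subject_id subject identifier (scalar character).
#' @param locus `"TRB"` (T-cell receptor beta) or `"IGH"` (immunoglobulin
#'   heavy chain).
#' @param normalized_to read depth the repertoire was rarefied to, or `NULL`
#'   if the repertoire holds raw (filtered) counts.
#' @param seed seed used for rarefaction, or `NULL`.
#'
#' @return An object of class `repertoire`: a list with elements
#'   `subject_id`, `locus`, `clonotypes`, `total_reads`, `normalized_to`,
#'   `seed`. `total_reads` is always the sum of `read_count`.
#' @export
#' @examples
#' rep <- repertoire(
#'   data.frame(cdr3_nt = c("TGTGCCAGC", "TGTGCCAGT"),
#'              read_count = c(10L, 5L)),
#'   subject_id = "S1", locus = "TRB")
#' rep$total_reads
repertoire <- function(clonotypes, subject_id, locus = c("TRB", "IGH"),
                       normalized_to = NULL, seed = NULL) {
  locus <- match.arg(locus)
  stopifnot(is.data.frame(clonotypes))
  clonotypes <- complete_clonotype_columns(clonotypes)
  obj <- structure(
    list(subject_id = as.character(subject_id),
         locus = locus,
         clonotypes = clonotypes,
         total_reads = sum(clonotypes$read_count),
         normalized_to = normalized_to,
         seed = seed),
    class = "repertoire")
  validate_repertoire(obj)
}

# Fill optional clonotype columns with defaults so downstream code can rely
# on a fixed schema.
complete_clonotype_columns <- function(df) {
  n <- nrow(df)
  if (is.null(df$cdr3_nt)) stop("clonotypes must have a 'cdr3_nt' column",
                                call. = FALSE)
  df$cdr3_nt <- toupper(as.character(df$cdr3_nt))
  if (is.null(df$cdr3_aa)) df$cdr3_aa <- translate_nt(df$cdr3_nt)
  if (is.null(df$v_gene)) df$v_gene <- rep(NA_character_, n)
  if (is.null(df$j_gene)) df$j_gene <- rep(NA_character_, n)
  if (is.null(df$read_count)) stop("clonotypes must have a 'read_count' column",
                                   call. = FALSE)
  df$read_count <- as.integer(df$read_count)
  if (is.null(df$productive)) df$productive <- rep(TRUE, n)
  if (is.null(df$v_identity_pct)) df$v_identity_pct <- rep(NA_real_, n)
  if (is.null(df$pgen)) df$pgen <- rep(NA_real_, n)
  rownames(df) <- NULL
  df[c("cdr3_nt", "cdr3_aa", "v_gene", "j_gene", "read_count", "productive",
       "v_identity_pct", "pgen")]
}

validate_repertoire <- function(x) {
  cl <- x$clonotypes
  if (anyDuplicated(cl$cdr3_nt)) {
    stop("duplicate cdr3_nt keys in repertoire; merge rows before construction",
         call. = FALSE)
  }
  if (nrow(cl) > 0L) {
    if (any(is.na(cl$read_count)) || any(cl$read_count < 1L)) {
      stop("read_count must be a positive integer for every clonotype",
           call. = FALSE)
    }
    if (any(!grepl("^[ACGT]+$", cl$cdr3_nt))) {
      stop("cdr3_nt must be a non-empty string over A/C/G/T", call. = FALSE)
    }
    ok_ident <- is.na(cl$v_identity_pct) |
      (cl$v_identity_pct >= 0 & cl$v_identity_pct <= 100)
    if (!all(ok_ident)) {
      stop("v_identity_pct must lie in [0, 100]", call. = FALSE)
    }
  }
  if (x$total_reads != sum(cl$read_count)) {
    stop("total_reads does not equal the sum of clonotype read counts",
         call. = FALSE)
  }
  if (!is.null(x$normalized_to) && x$total_reads != x$normalized_to) {
    stop("normalized repertoire must have total_reads == normalized_to",
         call. = FALSE)
  }
  x
}

#' @export
print.repertoire <- function(x, ...) {
  depth <- if (is.null(x$normalized_to)) "raw" else
    sprintf("normalized to %d reads", x$normalized_to)
  cat(sprintf("<repertoire> subject %s, locus %s: %d clonotypes, %d reads (%s)\n",
              x$subject_id, x$locus, nrow(x$clonotypes), x$total_reads, depth))
  invisible(x)
}
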