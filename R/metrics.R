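#' Clone frequency distribution of a repertoire
#'
#' Read frequencies p_i = read_count_i / total_reads, the abundance
#' distribution underlying Shannon/Simpson diversity and clonality.
#' Ordered by descending read count, ties broken by CDR3 nucleotide
#' sequence, so the vector is deterministic for a given repertoire.
#'
#' @param rep a [repertoire()] with at least one read.
#' @return Numeric vector of length `richness(rep)` summing to 1, named by
#'   `cdr3_nt`.
#' @export
clone_frequencies <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  cl <- rep$clonotypes
  if (nrow(cl) == 0L || rep$total_reads < 1L) {
    stop("cannot compute clone frequencies of an empty repertoire",
         call. = FALSE)
  }
  ord <- order(-cl$read_count, cl$cdr3_nt)
  p <- cl$read_count[ord] / rep$total_reads
  names(p) <- cl$cdr3_nt[ord]
  p
}

#' Shannon diversity H' in bits
#'
#' H' = -sum(p_i * log2(p_i)). Base-2 logarithms throughout, fixed by the
#' evenness definition J = H'/log2(S).
#'
#' @param p probability vector (strictly positive, sums to 1 within 1e-9).
#' @return H' in bits; 0 for a single-clone distribution.
#' @export
#' @examples
#' shannon_diversity(c(0.5, 0.5)) # exactly one bit
shannon_diversity <- function(p) {
  check_prob_vector(p)
  -sum(p * log2(p))
}

#' Simpson diversity 1 - sum(p^2)
#'
#' Diversity form of the Simpson index, disproportionately sensitive to the
#' most abundant clones. The concentration form sum(p^2) is available with
#' `concentration = TRUE`.
#'
#' @inheritParams shannon_diversity
#' @param concentration return sum(p^2) instead of 1 - sum(p^2).
#' @export
simpson_diversity <- function(p, concentration = FALSE) {
  check_prob_vector(p)
  s2 <- sum(p^2)
  if (concentration) s2 else 1 - s2
}

#' Repertoire clonality: 1 minus Pielou's evenness
#'
#' Clonality = 1 - J with J = H'/log2(S), H' the base-2 Shannon diversity
#' and S the number of clones. A value of 1 means the sample contains a
#' single clone; 0 means complete clonal diversity (all clones at equal
#' frequency). For S = 1 the evenness J is undefined (log2(1) = 0) and
#' clonality is defined as 1, the monoclonal limit.
#'
#' @inheritParams shannon_diversity
#' @export
#' @examples
#' clonality(rep(0.25, 4)) # perfectly even -> 0
#' clonality(1)            # monoclonal -> 1
clonality <- function(p) {
  check_prob_vector(p)
  S <- length(p)
  if (S == 1L) return(1)
  cl <- 1 - shannon_diversity(p) / log2(S)
  # guard floating residue at the uniform boundary
  if (cl < 0 && cl > -1e-9) cl <- 0
  cl
}

#' Richness: number of distinct clonotypes
#'
#' Richness is only comparable across subjects at a common read depth;
#' a warning is emitted for raw (non-normalized) repertoires.
#'
#' @param rep a [repertoire()].
#' @param warn_raw warn when the repertoire has not been normalized.
#' @return Integer count of unique CDR3 nucleotide clonotypes.
#' @export
richness <- function(rep, warn_raw = TRUE) {
  stopifnot(inherits(rep, "repertoire"))
  if (warn_raw && is.null(rep$normalized_to) && nrow(rep$clonotypes) > 0L) {
    warning("richness computed on a raw repertoire; normalize to a common ",
            "read depth before cross-subject comparison", call. = FALSE)
  }
  nrow(rep$clonotypes)
}

#' Mean CDR3 length in amino acids
#'
#' Arithmetic mean of amino-acid CDR3 lengths, unweighted over unique
#' clonotypes by default; `weighting = "read"` weights each clonotype by
#' its read count. Clonotypes with an empty (untranslatable) `cdr3_aa` are
#' excluded with a warning.
#'
#' @param rep a [repertoire()].
#' @param weighting `"clonotype"` (default) or `"read"`.
#' @export
mean_cdr3_length <- function(rep, weighting = c("clonotype", "read")) {
  stopifnot(inherits(rep, "repertoire"))
  weighting <- match.arg(weighting)
  cl <- rep$clonotypes
  ok <- !is.na(cl$cdr3_aa) & nchar(cl$cdr3_aa) > 0L
  if (!any(ok)) {
    stop("no clonotype has a non-empty cdr3_aa; cannot compute CDR3 length",
         call. = FALSE)
  }
  if (!all(ok)) {
    warning(sprintf("%d clonotype(s) without cdr3_aa excluded from CDR3 length",
                    sum(!ok)), call. = FALSE)
  }
  len <- nchar(cl$cdr3_aa[ok])
  if (weighting == "clonotype") mean(len)
  else stats::weighted.mean(len, cl$read_count[ok])
}

#' Somatic hypermutation fraction of an IGH repertoire
#'
#' A B-cell clonotype is called somatically hypermutated when its V-segment
#' germline identity is strictly below the threshold (default 98 percent;
#' a clone at exactly 98.0 is NOT mutated). The denominator is the number
#' of unique clonotypes; `weighting = "read"` weights by read count.
#'
#' @param rep an IGH [repertoire()] with `v_identity_pct` set for every
#'   clonotype.
#' @param identity_threshold_pct germline identity threshold in percent.
#' @param weighting `"clonotype"` (default) or `"read"`.
#' @return Fraction in \[0, 1\].
#' @export
shm_fraction <- function(rep, identity_threshold_pct = 98.0,
                         weighting = c("clonotype", "read")) {
  stopifnot(inherits(rep, "repertoire"))
  weighting <- match.arg(weighting)
  if (rep$locus != "IGH") {
    stop(sprintf("somatic hypermutation is defined for IGH repertoires, not %s",
                 rep$locus), call. = FALSE)
  }
  cl <- rep$clonotypes
  miss <- is.na(cl$v_identity_pct)
  if (any(miss)) {
    stop(sprintf("v_identity_pct missing for clonotype(s): %s",
                 paste(utils::head(cl$cdr3_nt[miss], 5), collapse = ", ")),
         call. = FALSE)
  }
  mutated <- cl$v_identity_pct < identity_threshold_pct
  if (weighting == "clonotype") mean(mutated)
  else stats::weighted.mean(mutated, cl$read_count)
}

#' V-gene usage matrix across repertoires
#'
#' Per-subject frequency of each V gene over the union of genes observed in
#' any repertoire; genes absent from a subject get 0 and every row sums
#' to 1. Default weighting counts each unique clonotype once; `"read"`
#' weights by read count.
#'
#' @param reps list of [repertoire()] objects (at least one) with `v_gene`
#'   set.
#' @param weighting `"clonotype"` or `"read"`.
#' @return Numeric matrix, rows = subjects (named by `subject_id`),
#'   columns = sorted V-gene names.
#' @export
v_usage <- function(reps, weighting = c("clonotype", "read")) {
  weighting <- match.arg(weighting)
  if (inherits(reps, "repertoire")) reps <- list(reps)
  stopifnot(length(reps) >= 1L, all(vapply(reps, inherits, logical(1),
                                           "repertoire")))
  genes <- sort(unique(unlist(lapply(reps, function(r) r$clonotypes$v_gene))))
  genes <- genes[!is.na(genes)]
  m <- matrix(0, nrow = length(reps), ncol = length(genes),
              dimnames = list(vapply(reps, `[[`, character(1), "subject_id"),
                              genes))
  for (i in seq_along(reps)) {
    cl <- reps[[i]]$clonotypes
    w <- if (weighting == "clonotype") rep(1, nrow(cl)) else cl$read_count
    tot <- tapply(w, factor(cl$v_gene, levels = genes), sum)
    tot[is.na(tot)] <- 0
    m[i, ] <- tot / sum(tot)
  }
  m
}

#' Principal component analysis of V-gene usage
#'
#' Column-centred PCA via eigendecomposition of the covariance matrix of
#' the usage frequencies. Loadings ranked by their contribution reproduce
#' the usual "V genes contributing most to repertoire skewing" ordering;
#' the even-contribution reference level is 1/n_genes.
#'
#' @param m usage matrix from [v_usage()] (rows = subjects).
#' @param n_components number of components to retain.
#' @return List with `scores` (subjects x components), `loadings`
#'   (genes x components), `explained_variance` (fractions, non-increasing),
#'   and `contribution` (per-gene fraction of retained variance, decreasing).
#' @export
usage_pca <- function(m, n_components = 2L) {
  stopifnot(is.matrix(m))
  if (nrow(m) < 2L) stop("PCA requires at least 2 subjects", call. = FALSE)
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > min(dim(m))) {
    stop("n_components must be between 1 and min(dim(m))", call. = FALSE)
  }
  centered <- scale(m, center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(centered), symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  total <- sum(vals)
  keep <- seq_len(n_components)
  loadings <- eig$vectors[, keep, drop = FALSE]
  rownames(loadings) <- colnames(m)
  colnames(loadings) <- paste0("PC", keep)
  scores <- centered %*% loadings
  colnames(scores) <- paste0("PC", keep)
  explained <- if (total > 0) vals[keep] / total else rep(0, n_components)
  contrib <- if (total > 0) {
    rowSums(sweep(loadings^2, 2, vals[keep], `*`)) / total
  } else {
    stats::setNames(rep(0, ncol(m)), colnames(m))
  }
  list(scores = scores,
       loadings = loadings,
       explained_variance = explained,
       contribution = sort(contrib, decreasing = TRUE))
}

#' Bundle all single-repertoire statistics
#'
#' Computes the full per-repertoire metric set: clonality, Shannon (bits)
#' and Simpson diversity, richness, evenness, mean CDR3 length, somatic
#' hypermutation fraction (IGH only), and - when a generative model is
#' supplied or Pgen values are already annotated - the mean generation
#' probability and the public-clonotype fraction (clones with
#' Pgen > `public_threshold`; high-Pgen clones are the ones frequently
#' shared between individuals).
#'
#' @param rep a filtered, normalized [repertoire()].
#' @param pgen_model optional [generative_model()]; when supplied the
#'   repertoire is annotated via [annotate_pgen()] first.
#' @param public_threshold Pgen above which a clonotype is called public
#'   (default 1e-9).
#' @param cdr3_weighting passed to [mean_cdr3_length()].
#' @return Object of class `repertoire_metrics` (named list) with fields
#'   `subject_id`, `locus`, `clonality`, `shannon_bits`,
#'   `simpson_diversity`, `richness`, `evenness`, `mean_cdr3_len_aa`,
#'   `shm_fraction`, `mean_pgen`, `public_fraction`.
#' @export
repertoire_metrics <- function(rep, pgen_model = NULL, public_threshold = 1e-9,
                               cdr3_weighting = "clonotype") {
  stopifnot(inherits(rep, "repertoire"))
  if (!is.null(pgen_model)) rep <- annotate_pgen(rep, pgen_model)
  p <- clone_frequencies(rep)
  S <- richness(rep, warn_raw = FALSE)
  cl <- clonality(p)
  mean_len <- tryCatch(mean_cdr3_length(rep, weighting = cdr3_weighting),
                       error = function(e) NA_real_)
  shm <- if (rep$locus == "IGH" && !anyNA(rep$clonotypes$v_identity_pct)) {
    shm_fraction(rep)
  } else {
    NA_real_
  }
  pg <- rep$clonotypes$pgen
  have_pgen <- !all(is.na(pg))
  structure(
    list(subject_id = rep$subject_id,
         locus = rep$locus,
         clonality = cl,
         shannon_bits = shannon_diversity(p),
         simpson_diversity = simpson_diversity(p),
         richness = S,
         evenness = 1 - cl,
         mean_cdr3_len_aa = mean_len,
         shm_fraction = shm,
         mean_pgen = if (have_pgen) mean(pg) else NA_real_,
         public_fraction = if (have_pgen) mean(pg > public_threshold)
                           else NA_real_),
    class = "repertoire_metrics")
}

#' @export
print.repertoire_metrics <- function(x, ...) {
  cat(sprintf("<repertoire_metrics> %s (%s)\n", x$subject_id, x$locus))
  flds <- setdiff(names(x), c("subject_id", "locus"))
  for (f in flds) cat(sprintf("  %-18s %s\n", f, format(x[[f]], digits = 6)))
  invisible(x)
}

#' Metrics table for a set of repertoires
#'
#' Applies [repertoire_metrics()] to each repertoire and stacks the results
#' into a data.frame, one row per subject and locus.
#'
#' @inheritParams repertoire_metrics
#' @param reps list of repertoires.
#' @return data.frame with one row per repertoire.
#' @export
metrics_table <- function(reps, pgen_model = NULL, public_threshold = 1e-9) {
  rows <- lapply(reps, function(r) {
    m <- repertoire_metrics(r, pgen_model = pgen_model,
                            public_threshold = public_threshold)
    as.data.frame(unclass(m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
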