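#' Default AIRR rearrangement column mapping
#'
#' Maps the internal clonotype fields to the column names of the AIRR
#' Rearrangement schema. Override entries (e.g. for MiXCR `exportClones`
#' headers) by passing a modified copy to [read_clonotype_table()].
#'
#' @return Named character vector: internal field -> column name.
#' @export
airr_column_map <- function() {
  c(cdr3_nt = "junction",
    cdr3_aa = "junction_aa",
    v_gene = "v_call",
    j_gene = "j_call",
    read_count = "duplicate_count",
    productive = "productive",
    v_identity_pct = "v_identity")
}

#' Read a clonotype table into a repertoire
#'
#' Parses a tab-separated clonotype table (AIRR rearrangement dialect by
#' default). Rows sharing the same CDR3 nucleotide sequence are merged by
#' summing their read counts; the V/J call of the merged clone is the
#' read-count majority call, ties broken lexicographically.
#'
#' @param path path to a TSV file with a header row.
#' @param column_map named character vector mapping internal fields
#'   (`cdr3_nt`, `v_gene`, `j_gene`, `read_count`, `productive`,
#'   `v_identity_pct`, optionally `cdr3_aa`) to file columns. Defaults to
#'   [airr_column_map()]. The `cdr3_aa` and `v_identity_pct` columns are
#'   optional in the file; all others are required.
#' @param locus `"TRB"` or `"IGH"`.
#' @param subject_id subject identifier; defaults to the file name without
#'   extension.
#' @return A [repertoire()] object.
#' @export
read_clonotype_table <- function(path, column_map = airr_column_map(),
                                 locus = c("TRB", "IGH"), subject_id = NULL) {
  locus <- match.arg(locus)
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  cmap <- airr_column_map()
  cmap[names(column_map)] <- column_map
  raw <- read_tsv(path, colClasses = "character")

  required <- c("cdr3_nt", "v_gene", "j_gene", "read_count", "productive")
  for (field in required) {
    if (!cmap[[field]] %in% names(raw)) {
      stop(sprintf("clonotype table '%s' lacks required column '%s'",
                   basename(path), cmap[[field]]), call. = FALSE)
    }
  }
  optional_present <- function(field) cmap[[field]] %in% names(raw)

  counts_chr <- raw[[cmap[["read_count"]]]]
  counts <- suppressWarnings(as.numeric(counts_chr))
  bad <- which(is.na(counts) | counts != floor(counts))
  if (length(bad) > 0L) {
    stop(sprintf("non-integer read_count '%s' at row %d of '%s'",
                 counts_chr[bad[1]], bad[1], basename(path)), call. = FALSE)
  }

  df <- data.frame(
    cdr3_nt = toupper(raw[[cmap[["cdr3_nt"]]]]),
    cdr3_aa = if (optional_present("cdr3_aa")) raw[[cmap[["cdr3_aa"]]]] else NA_character_,
    v_gene = raw[[cmap[["v_gene"]]]],
    j_gene = raw[[cmap[["j_gene"]]]],
    read_count = as.integer(counts),
    productive = parse_logical(raw[[cmap[["productive"]]]]),
    v_identity_pct = if (optional_present("v_identity_pct"))
      as.numeric(raw[[cmap[["v_identity_pct"]]]]) else NA_real_,
    pgen = NA_real_,
    stringsAsFactors = FALSE)
  if (!optional_present("cdr3_aa")) df$cdr3_aa <- translate_nt(df$cdr3_nt)

  merged <- merge_clonotype_rows(df)
  repertoire(merged, subject_id = subject_id, locus = locus)
}

parse_logical <- function(x) {
  up <- toupper(trimws(x))
  out <- rep(NA, length(x))
  out[up %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[up %in% c("FALSE", "F", "0", "NO")] <- FALSE
  if (anyNA(out)) {
    stop(sprintf("cannot parse logical value '%s'", x[which(is.na(out))[1]]),
         call. = FALSE)
  }
  out
}

# Merge rows sharing cdr3_nt: counts are summed; categorical fields take the
# read-count majority value with lexicographic tie-break (determinism).
merge_clonotype_rows <- function(df) {
  if (!anyDuplicated(df$cdr3_nt)) return(df)
  pieces <- split(df, df$cdr3_nt)
  merged <- lapply(pieces, function(g) {
    if (nrow(g) == 1L) return(g)
    majority <- function(vals) {
      w <- tapply(g$read_count, vals, sum)
      names(w)[order(-w, names(w))][1]
    }
    rep_row <- g[order(-g$read_count, g$v_gene, g$j_gene), , drop = FALSE][1, ]
    rep_row$read_count <- sum(g$read_count)
    rep_row$v_gene <- majority(g$v_gene)
    rep_row$j_gene <- majority(g$j_gene)
    rep_row
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out[order(out$cdr3_nt), , drop = FALSE]
}

#' Write a repertoire as an AIRR rearrangement TSV
#'
#' The inverse of [read_clonotype_table()]: column names follow
#' [airr_column_map()]; numeric fields are written at full precision so
#' that read -> write -> read round-trips preserve every field.
#'
#' @param rep a [repertoire()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(rep, path) {
  stopifnot(inherits(rep, "repertoire"))
  cl <- rep$clonotypes
  out <- data.frame(
    junction = cl$cdr3_nt,
    junction_aa = cl$cdr3_aa,
    v_call = cl$v_gene,
    j_call = cl$j_gene,
    duplicate_count = cl$read_count,
    productive = ifelse(cl$productive, "TRUE", "FALSE"),
    v_identity = cl$v_identity_pct,
    pgen = cl$pgen,
    stringsAsFactors = FALSE)
  write_tsv(out, path)
}

#' Filter a repertoire by productivity and minimum read count
#'
#' Applies the standard AIRR-seq preprocessing rule: non-productive
#' rearrangements and clones supported by fewer than `min_count` reads are
#' removed before any diversity statistic is computed. Filtering precedes
#' rarefaction; reversing the order changes richness because singleton
#' clones would then survive into the subsampled pool.
#'
#' @param rep a [repertoire()].
#' @param min_count minimum read count to keep a clonotype (default 2, i.e.
#'   singletons removed).
#' @param productive_only drop non-productive clonotypes (default `TRUE`).
#' @return A new repertoire; the input is unmodified. An empty result is
#'   legal. Any previous normalization state is cleared because filtering
#'   changes the read total.
#' @export
filter_repertoire <- function(rep, min_count = 2L, productive_only = TRUE) {
  stopifnot(inherits(rep, "repertoire"))
  if (!is_scalar_int(min_count) || min_count < 1) {
    stop("min_count must be an integer >= 1", call. = FALSE)
  }
  keep <- rep$clonotypes$read_count >= min_count
  if (productive_only) keep <- keep & rep$clonotypes$productive
  cl <- rep$clonotypes[keep, , drop = FALSE]
  rownames(cl) <- NULL
  out <- rep
  out$clonotypes <- cl
  out$total_reads <- sum(cl$read_count)
  out$normalized_to <- NULL
  out
}

#' Rarefy a repertoire to a fixed read depth
#'
#' Draws `target` reads without replacement from the repertoire's read pool
#' (each clonotype contributing `read_count` indistinguishable reads), i.e.
#' the per-clone sampled counts follow the multivariate hypergeometric
#' distribution. Clonotypes receiving zero sampled reads are dropped.
#' Sampling with replacement (multinomial on read frequencies) is available
#' via `replace = TRUE` but is not the default: rarefaction is the standard
#' reading of normalising repertoires "to" a fixed read count.
#'
#' @param rep a [repertoire()], typically already filtered.
#' @param target read depth to sample down to (e.g. 50000 within-cohort,
#'   30000 when comparing against shallower control repertoires).
#' @param seed integer seed; the result is reproducible for a fixed seed.
#' @param replace sample with replacement instead of rarefying.
#' @return A repertoire with `total_reads == target` exactly,
#'   `normalized_to = target` and `seed` recorded.
#' @export
downsample_reads <- function(rep, target, seed, replace = FALSE) {
  stopifnot(inherits(rep, "repertoire"))
  if (!is_scalar_int(target) || target < 1) {
    stop("target must be an integer >= 1", call. = FALSE)
  }
  if (!is_scalar_int(seed)) stop("seed must be an integer", call. = FALSE)
  if (rep$total_reads < target) {
    stop(sprintf(
      "read depth %d is below the normalization target %d for subject %s",
      rep$total_reads, target, rep$subject_id), call. = FALSE)
  }
  counts <- rep$clonotypes$read_count
  new_counts <- with_seed(seed, {
    if (replace) {
      as.integer(stats::rmultinom(1, target, counts / sum(counts)))
    } else {
      sample_hypergeometric(counts, target)
    }
  })
  keep <- new_counts > 0L
  cl <- rep$clonotypes[keep, , drop = FALSE]
  cl$read_count <- new_counts[keep]
  rownames(cl) <- NULL
  out <- rep
  out$clonotypes <- cl
  out$total_reads <- sum(cl$read_count)
  out$normalized_to <- as.integer(target)
  out$seed <- as.integer(seed)
  validate_repertoire(out)
}

# Sequential conditional sampling of the multivariate hypergeometric:
# clone i receives Hypergeometric(m = counts[i], n = remaining pool,
# k = reads still needed). O(number of clones).
sample_hypergeometric <- function(counts, target) {
  out <- integer(length(counts))
  pool_left <- sum(counts)
  need <- target
  for (i in seq_along(counts)) {
    if (need == 0L) break
    pool_left <- pool_left - counts[i]
    x <- stats::rhyper(1, counts[i], pool_left, need)
    out[i] <- x
    need <- need - x
  }
  out
}
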