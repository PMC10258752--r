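#' A simplified V(D)J generative model
#'
#' Antigen receptors are generated stochastically by genetic recombination;
#' the probability that the process produces a given CDR3 nucleotide
#' sequence (its generation probability, Pgen) separates frequently shared
#' "public" clonotypes from rarely shared "private" ones. This model is a
#' deliberately simplified, exactly enumerable stand-in for full
#' IGoR-parameterized machinery: a V-segment suffix is chosen and trimmed
#' at its 3' end, an untemplated insertion of i.i.d. bases is added, and a
#' J-segment prefix trimmed at its 5' end is appended. D segments and
#' per-position insertion context are omitted; the model supports exact
#' (non-Monte-Carlo) Pgen computation and forward simulation.
#'
#' Trimming removes `min(t, nchar(segment))` bases, so a trim may reduce a
#' segment to the empty string.
#'
#' @param v_segments data.frame with columns `name`, `seq` (3' suffix
#'   contributing to the junction), `prob`.
#' @param j_segments data.frame with columns `name`, `seq` (5' prefix
#'   contributing to the junction), `prob`.
#' @param insertion_length_probs probability vector over insertion lengths
#'   0..L_max (element k is the probability of length k-1).
#' @param insertion_base_probs probability vector over A, C, G, T.
#' @param v_trim_probs,j_trim_probs probability vectors over trim lengths
#'   0..T_max.
#' @return Object of class `generative_model`.
#' @export
#' @examples
#' m <- generative_model(
#'   v_segments = data.frame(name = c("V1", "V2"), seq = c("AC", "GG"),
#'                           prob = c(0.5, 0.5)),
#'   j_segments = data.frame(name = c("J1", "J2"), seq = c("GT", "TT"),
#'                           prob = c(0.5, 0.5)),
#'   insertion_length_probs = 1)   # always zero insertions, no trimming
#' pgen_nt("ACGT", m)  # 0.5 * 0.5 = 0.25
generative_model <- function(v_segments, j_segments,
                             insertion_length_probs = c(0.2, 0.3, 0.3, 0.2),
                             insertion_base_probs = rep(0.25, 4),
                             v_trim_probs = 1,
                             j_trim_probs = 1) {
  stopifnot(is.data.frame(v_segments), is.data.frame(j_segments))
  for (d in list(v_segments, j_segments)) {
    if (!all(c("name", "seq", "prob") %in% names(d))) {
      stop("segment tables need columns name, seq, prob", call. = FALSE)
    }
    if (any(nchar(d$seq) == 0L) || any(!grepl("^[ACGT]+$", d$seq))) {
      stop("segment sequences must be non-empty strings over A/C/G/T",
           call. = FALSE)
    }
  }
  check_prob_vector(v_segments$prob, "v_segments$prob", positive = FALSE)
  check_prob_vector(j_segments$prob, "j_segments$prob", positive = FALSE)
  check_prob_vector(insertion_length_probs, "insertion_length_probs",
                    positive = FALSE)
  check_prob_vector(insertion_base_probs, "insertion_base_probs",
                    positive = FALSE)
  if (length(insertion_base_probs) != 4L) {
    stop("insertion_base_probs must have 4 entries (A, C, G, T)",
         call. = FALSE)
  }
  check_prob_vector(v_trim_probs, "v_trim_probs", positive = FALSE)
  check_prob_vector(j_trim_probs, "j_trim_probs", positive = FALSE)
  structure(
    list(v_segments = data.frame(name = as.character(v_segments$name),
                                 seq = toupper(v_segments$seq),
                                 prob = v_segments$prob,
                                 stringsAsFactors = FALSE),
         j_segments = data.frame(name = as.character(j_segments$name),
                                 seq = toupper(j_segments$seq),
                                 prob = j_segments$prob,
                                 stringsAsFactors = FALSE),
         insertion_length_probs = unname(insertion_length_probs),
         insertion_base_probs = stats::setNames(unname(insertion_base_probs),
                                                c("A", "C", "G", "T")),
         v_trim_probs = unname(v_trim_probs),
         j_trim_probs = unname(j_trim_probs)),
    class = "generative_model")
}

#' @export
print.generative_model <- function(x, ...) {
  cat(sprintf(
    "<generative_model> %d V, %d J segments; insertions 0..%d nt; trims V 0..%d, J 0..%d\n",
    nrow(x$v_segments), nrow(x$j_segments),
    length(x$insertion_length_probs) - 1L,
    length(x$v_trim_probs) - 1L, length(x$j_trim_probs) - 1L))
  invisible(x)
}

#' Default toy TRB-like generative model
#'
#' A small model used by the simulator: four V suffixes and four J prefixes
#' with unequal usage, insertions of 0-6 bases, and up to 2 nt trimming on
#' each side. Sequence lengths are multiples of 3 plus trims/insertions, so
#' a sizeable fraction of junctions translate in frame.
#'
#' @param v_probs optional override of the V-segment usage probabilities
#'   (length 4, summing to 1).
#' @return A [generative_model()].
#' @export
default_model <- function(v_probs = NULL) {
  v <- data.frame(
    name = c("TRBV05-1", "TRBV06-2", "TRBV19-1", "TRBV28-1"),
    seq = c("TGTGCCAGCAGC", "TGTGCCAGTTCA", "TGTGCCACCAGC", "TGTGCCAGCTCG"),
    prob = c(0.35, 0.30, 0.20, 0.15),
    stringsAsFactors = FALSE)
  if (!is.null(v_probs)) {
    check_prob_vector(v_probs, "v_probs", positive = FALSE)
    stopifnot(length(v_probs) == nrow(v))
    v$prob <- v_probs
  }
  j <- data.frame(
    name = c("TRBJ01-1", "TRBJ01-2", "TRBJ02-1", "TRBJ02-7"),
    seq = c("AACACTGAAGCTTTCTTT", "AACTATGGCTACACCTTC",
            "AATGAGCAGTTCTTC", "TCCTACGAGCAGTACTTC"),
    prob = c(0.30, 0.25, 0.25, 0.20),
    stringsAsFactors = FALSE)
  generative_model(
    v_segments = v, j_segments = j,
    insertion_length_probs = c(0.10, 0.15, 0.20, 0.25, 0.15, 0.10, 0.05),
    insertion_base_probs = c(0.22, 0.28, 0.30, 0.20),
    v_trim_probs = c(0.5, 0.3, 0.2),
    j_trim_probs = c(0.5, 0.3, 0.2))
}

# Probability that a trimmed segment equals a given string:
# left[k] = P(trimmed V piece == first k characters of seq), k = 0..n
# right[m] analogous for the J side on suffixes.
side_match_probs <- function(seq, segments, trim_probs, side = c("v", "j")) {
  side <- match.arg(side)
  n <- nchar(seq)
  acc <- numeric(n + 1L)  # index k+1 holds piece length k
  for (i in seq_len(nrow(segments))) {
    seg <- segments$seq[i]
    p_seg <- segments$prob[i]
    len <- nchar(seg)
    for (t in seq_along(trim_probs) - 1L) {
      k <- max(0L, len - t)
      if (k > n) next
      piece <- if (k == 0L) "" else if (side == "v") {
        substr(seg, 1L, k)
      } else {
        substr(seg, len - k + 1L, len)
      }
      target <- if (k == 0L) "" else if (side == "v") {
        substr(seq, 1L, k)
      } else {
        substr(seq, n - k + 1L, n)
      }
      if (piece == target) {
        acc[k + 1L] <- acc[k + 1L] + p_seg * trim_probs[t + 1L]
      }
    }
  }
  acc
}

#' Generation probability of a CDR3 nucleotide sequence
#'
#' Exact Pgen under a [generative_model()]: the sum, over every event tuple
#' (V segment, V trim, insertion, J trim, J segment) whose concatenation
#' equals `seq`, of the product of event probabilities. Computed by dynamic
#' programming over the V/insertion/J split positions rather than by
#' enumeration, so it is exact and fast for arbitrary sequences.
#'
#' @param seq CDR3 nucleotide string over A/C/G/T.
#' @param model a [generative_model()].
#' @return Probability in \[0, 1\]; 0 for sequences the model cannot
#'   generate.
#' @export
pgen_nt <- function(seq, model) {
  stopifnot(inherits(model, "generative_model"))
  if (length(seq) != 1L || is.na(seq)) stop("seq must be a single string",
                                            call. = FALSE)
  seq <- toupper(seq)
  if (!grepl("^[ACGT]*$", seq)) {
    stop(sprintf("invalid characters in sequence '%s'", seq), call. = FALSE)
  }
  n <- nchar(seq)
  left <- side_match_probs(seq, model$v_segments, model$v_trim_probs, "v")
  right <- side_match_probs(seq, model$j_segments, model$j_trim_probs, "j")
  ins_len <- model$insertion_length_probs
  base_p <- model$insertion_base_probs
  chars <- if (n > 0L) strsplit(seq, "")[[1]] else character(0)
  char_p <- if (n > 0L) unname(base_p[chars]) else numeric(0)
  # cumulative product of base probabilities: prefix_prod[i+1] = prod(1..i)
  prefix_prod <- c(1, cumprod(char_p))
  total <- 0
  for (k in 0:n) {            # V piece covers positions 1..k
    if (left[k + 1L] == 0) next
    for (m in 0:(n - k)) {    # J piece covers the last m positions
      if (right[m + 1L] == 0) next
      l_ins <- n - k - m
      if (l_ins + 1L > length(ins_len)) next
      p_ins <- ins_len[l_ins + 1L]
      if (p_ins == 0) next
      p_bases <- prefix_prod[k + l_ins + 1L] / prefix_prod[k + 1L]
      total <- total + left[k + 1L] * p_ins * p_bases * right[m + 1L]
    }
  }
  total
}

#' Sample one rearrangement from a generative model
#'
#' Forward sampler paired with [pgen_nt()]: draws each recombination event
#' (V choice, V trim, insertion length and bases, J trim, J choice) from
#' its distribution and returns the concatenated sequence plus the events.
#'
#' @param model a [generative_model()].
#' @param seed integer seed; identical seeds give identical draws.
#' @return List with `seq` (nucleotide string, possibly empty under extreme
#'   trimming) and `events` (named list of the drawn events).
#' @export
sample_rearrangement <- function(model, seed) {
  stopifnot(inherits(model, "generative_model"))
  with_seed(seed, sample_rearrangement_impl(model))
}

# Unseeded single draw, used in loops that manage their own RNG stream.
sample_rearrangement_impl <- function(model) {
  vi <- sample.int(nrow(model$v_segments), 1L, prob = model$v_segments$prob)
  ji <- sample.int(nrow(model$j_segments), 1L, prob = model$j_segments$prob)
  tv <- sample.int(length(model$v_trim_probs), 1L,
                   prob = model$v_trim_probs) - 1L
  tj <- sample.int(length(model$j_trim_probs), 1L,
                   prob = model$j_trim_probs) - 1L
  li <- sample.int(length(model$insertion_length_probs), 1L,
                   prob = model$insertion_length_probs) - 1L
  ins <- if (li > 0L) {
    paste0(sample(c("A", "C", "G", "T"), li, replace = TRUE,
                  prob = model$insertion_base_probs), collapse = "")
  } else ""
  vseq <- model$v_segments$seq[vi]
  jseq <- model$j_segments$seq[ji]
  vpiece <- substr(vseq, 1L, max(0L, nchar(vseq) - tv))
  jpiece <- substr(jseq, min(nchar(jseq) + 1L, tj + 1L), nchar(jseq))
  list(seq = paste0(vpiece, ins, jpiece),
       events = list(v_name = model$v_segments$name[vi],
                     v_trim = tv,
                     insertion = ins,
                     j_trim = tj,
                     j_name = model$j_segments$name[ji]))
}

#' Annotate a repertoire with generation probabilities
#'
#' Sets each clonotype's `pgen` field via [pgen_nt()] on its CDR3
#' nucleotide sequence. Sequences the model cannot generate receive
#' Pgen 0 and are reported in a message. The input is unmodified;
#' repeated calls are idempotent.
#'
#' @param rep a filtered [repertoire()].
#' @param model a [generative_model()].
#' @return A copy of `rep` with `pgen` filled in.
#' @export
annotate_pgen <- function(rep, model) {
  stopifnot(inherits(rep, "repertoire"), inherits(model, "generative_model"))
  out <- rep
  out$clonotypes$pgen <- vapply(out$clonotypes$cdr3_nt, pgen_nt, numeric(1),
                                model = model, USE.NAMES = FALSE)
  n_zero <- sum(out$clonotypes$pgen == 0)
  if (n_zero > 0L) {
    message(sprintf("%d clonotype(s) unreachable under the model (Pgen 0) for subject %s",
                    n_zero, rep$subject_id))
  }
  out
}

#' Serialize a generative model to JSON
#'
#' @param model a [generative_model()].
#' @param path output path for a structured text config.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "generative_model"))
  jsonlite::write_json(unclass(model), path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a generative model from JSON
#'
#' @param path a config written by [write_model()].
#' @return A [generative_model()].
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  generative_model(
    v_segments = as.data.frame(x$v_segments),
    j_segments = as.data.frame(x$j_segments),
    insertion_length_probs = x$insertion_length_probs,
    insertion_base_probs = unlist(x$insertion_base_probs),
    v_trim_probs = x$v_trim_probs,
    j_trim_probs = x$j_trim_probs)
}
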