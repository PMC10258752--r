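# Fixture builders and independent oracles shared across test files.

toy_repertoire <- function(counts, locus = "TRB", subject_id = "S1",
                           productive = TRUE, v_identity = NA_real_,
                           cdr3_aa = NULL, v_gene = NULL) {
  n <- length(counts)
  # distinct deterministic CDR3s: vary a middle base block by index
  nts <- vapply(seq_len(n), function(i) {
    paste0("TGT", paste(rep(c("GCC", "AGC", "ACC", "TCC")[(i %% 4) + 1],
                            (i %/% 4) + 1), collapse = ""), "TTT")
  }, character(1))
  stopifnot(!anyDuplicated(nts))
  df <- data.frame(cdr3_nt = nts,
                   read_count = as.integer(counts),
                   productive = rep_len(productive, n),
                   v_identity_pct = rep_len(v_identity, n),
                   stringsAsFactors = FALSE)
  if (!is.null(cdr3_aa)) df$cdr3_aa <- cdr3_aa
  if (!is.null(v_gene)) df$v_gene <- v_gene
  repertoire(df, subject_id = subject_id, locus = locus)
}

# 2V x 2J model with no trimming and no insertions: 4 equally likely
# sequences ACGT, ACTT, GGGT, GGTT, each Pgen 0.25.
toy_model <- function() {
  generative_model(
    v_segments = data.frame(name = c("V1", "V2"), seq = c("AC", "GG"),
                            prob = c(0.5, 0.5)),
    j_segments = data.frame(name = c("J1", "J2"), seq = c("GT", "TT"),
                            prob = c(0.5, 0.5)),
    insertion_length_probs = 1)
}

random_toy_model <- function(seed) {
  set.seed(seed)
  rand_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")
  rand_probs <- function(k) { p <- runif(k) + 0.05; p / sum(p) }
  nv <- sample(1:3, 1); nj <- sample(1:3, 1)
  l_max <- sample(0:3, 1)
  tv_max <- sample(0:2, 1); tj_max <- sample(0:2, 1)
  generative_model(
    v_segments = data.frame(name = paste0("V", seq_len(nv)),
                            seq = vapply(seq_len(nv), function(i)
                              rand_seq(sample(2:4, 1)), character(1)),
                            prob = rand_probs(nv)),
    j_segments = data.frame(name = paste0("J", seq_len(nj)),
                            seq = vapply(seq_len(nj), function(i)
                              rand_seq(sample(2:4, 1)), character(1)),
                            prob = rand_probs(nj)),
    insertion_length_probs = rand_probs(l_max + 1),
    insertion_base_probs = rand_probs(4),
    v_trim_probs = rand_probs(tv_max + 1),
    j_trim_probs = rand_probs(tj_max + 1))
}

# Independent Pgen oracle: exhaustive enumeration over every event tuple
# (V, v_trim, insertion string, j_trim, J). Returns a named vector of the
# total generation probability of each reachable sequence.
enumerate_pgen_table <- function(model) {
  bases <- c("A", "C", "G", "T")
  all_insertions <- function(l) {
    if (l == 0) return(list(""))
    grid <- do.call(expand.grid, rep(list(bases), l))
    apply(grid, 1, paste, collapse = "")
  }
  ins_prob <- function(s) {
    if (nchar(s) == 0) return(1)
    prod(model$insertion_base_probs[strsplit(s, "")[[1]]])
  }
  acc <- new.env()
  add <- function(seq, p) {
    key <- paste0("k", seq)
    assign(key, (if (exists(key, acc)) get(key, acc) else 0) + p, acc)
  }
  for (vi in seq_len(nrow(model$v_segments))) {
    vseq <- model$v_segments$seq[vi]
    for (tv in seq_along(model$v_trim_probs) - 1) {
      vpiece <- substr(vseq, 1, max(0, nchar(vseq) - tv))
      p_v <- model$v_segments$prob[vi] * model$v_trim_probs[tv + 1]
      for (li in seq_along(model$insertion_length_probs) - 1) {
        p_l <- model$insertion_length_probs[li + 1]
        if (p_l == 0) next
        for (ins in all_insertions(li)) {
          p_ins <- p_l * ins_prob(ins)
          for (ji in seq_len(nrow(model$j_segments))) {
            jseq <- model$j_segments$seq[ji]
            for (tj in seq_along(model$j_trim_probs) - 1) {
              jpiece <- substr(jseq, min(nchar(jseq) + 1, tj + 1),
                               nchar(jseq))
              p_j <- model$j_segments$prob[ji] * model$j_trim_probs[tj + 1]
              add(paste0(vpiece, ins, jpiece), p_v * p_ins * p_j)
            }
          }
        }
      }
    }
  }
  keys <- ls(acc)
  out <- vapply(keys, get, numeric(1), envir = acc)
  names(out) <- sub("^k", "", keys)
  out
}

# Kahan-compensated direct summation oracles for the diversity formulas,
# independent of the package implementations.
kahan_sum <- function(x) {
  s <- 0; c <- 0
  for (v in x) {
    y <- v - c
    t <- s + y
    c <- (t - s) - y
    s <- t
  }
  s
}
oracle_shannon <- function(p) kahan_sum(-p * log(p) / log(2))
oracle_simpson <- function(p) 1 - kahan_sum(p * p)
oracle_clonality <- function(p) {
  if (length(p) == 1) 1 else 1 - oracle_shannon(p) / (log(length(p)) / log(2))
}

# Diary whose qualifying days are exactly `qual_days`, via a single
# A-symptom (fever); horizon extends past the last day.
make_diary <- function(qual_days, horizon = max(qual_days) + 10,
                       unrecorded = integer(0), subject_id = "S1",
                       two_b = FALSE) {
  d <- data.frame(day = 0:horizon, recorded = TRUE)
  if (two_b) {
    d$dry_cough <- d$day %in% qual_days
    d$sore_throat <- d$day %in% qual_days
  } else {
    d$fever <- d$day %in% qual_days
  }
  d$recorded[d$day %in% unrecorded] <- FALSE
  for (col in setdiff(names(d), c("day", "recorded"))) {
    d[[col]][!d$recorded] <- FALSE
  }
  symptom_diary(d, subject_id)
}

write_fixture_tsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
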