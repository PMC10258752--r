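#' Define a synthetic cohort scenario
#'
#' Collects every knob of the synthetic-data generator. The defaults
#' describe an infant AIRR-seq cohort of the kind the pipeline targets:
#' 120 subjects sequenced to 50,000 reads, diary follow-up over the first
#' four years of life, a mean of roughly 30 cumulative infections by age 4
#' (`beta0 = 3.4` on the log scale), a modest protective effect of
#' repertoire breadth (`beta_metric = -0.1` per SD) and an older-sibling
#' effect (`beta_sib = 0.15`). Clone abundances follow a symmetric
#' Dirichlet-multinomial; the subject-level latent trait `z` scales the
#' Dirichlet concentration (`alpha_i = clone_concentration * exp(z_i)`), so
#' higher `z` means a more even, more diverse repertoire, and the same `z`
#' lowers the infection rate when `beta_metric < 0`.
#'
#' @param n_subjects number of children.
#' @param clone_concentration baseline symmetric Dirichlet concentration
#'   alpha (> 0); small values give dominated, clonal repertoires.
#' @param n_clones clones per repertoire. The default 2000 is a desk-scale
#'   stand-in for real repertoires (tens of thousands of clones), bounded
#'   by the sequence space of the toy recombination model.
#' @param reads_per_subject sequencing depth before normalization.
#' @param shm_mutated_fraction fraction of IGH clones carrying somatic
#'   hypermutation (germline identity drawn uniformly on \[90, 98)); naive
#'   clones get identity 100. Ignored for TRB.
#' @param nonproductive_fraction fraction of additional out-of-frame clones
#'   injected to exercise the productivity filter.
#' @param v_gene_probs optional V-segment usage vector for
#'   [default_model()].
#' @param beta0,beta_metric,beta_sib log-linear model of the cumulative
#'   episode count: `N_i ~ Poisson(exp(beta0 + beta_metric * z_i +
#'   beta_sib * sib_i))`.
#' @param episode_duration_days length of each planted episode.
#' @param gap_days minimum separation between planted episodes is
#'   `gap_days + 1` non-qualifying days, so episode calling at this gap can
#'   recover them exactly.
#' @param diary_missing_prob per-day probability that the diary entry is
#'   missing (symptoms unobserved).
#' @param follow_up_days diary length (default four 365-day years).
#' @param locus `"TRB"` or `"IGH"`.
#' @param prob_older_siblings probability a child has older siblings.
#' @param seed master seed for [simulate_cohort()].
#' @return List of class `cohort_scenario`.
#' @export
cohort_scenario <- function(n_subjects = 120L,
                            clone_concentration = 2,
                            n_clones = 2000L,
                            reads_per_subject = 50000L,
                            shm_mutated_fraction = 0.05,
                            nonproductive_fraction = 0.05,
                            v_gene_probs = NULL,
                            beta0 = 3.4,
                            beta_metric = -0.1,
                            beta_sib = 0.15,
                            episode_duration_days = 5L,
                            gap_days = 3L,
                            diary_missing_prob = 0.1,
                            follow_up_days = 1460L,
                            locus = c("TRB", "IGH"),
                            prob_older_siblings = 0.4,
                            seed = 1L) {
  locus <- match.arg(locus)
  stopifnot(n_subjects >= 1, clone_concentration > 0, n_clones >= 1,
            reads_per_subject >= 1,
            shm_mutated_fraction >= 0, shm_mutated_fraction <= 1,
            nonproductive_fraction >= 0, nonproductive_fraction < 1,
            diary_missing_prob >= 0, diary_missing_prob <= 1,
            episode_duration_days >= 1, follow_up_days >= 1)
  structure(
    list(n_subjects = as.integer(n_subjects),
         clone_concentration = clone_concentration,
         n_clones = as.integer(n_clones),
         reads_per_subject = as.integer(reads_per_subject),
         shm_mutated_fraction = shm_mutated_fraction,
         nonproductive_fraction = nonproductive_fraction,
         v_gene_probs = v_gene_probs,
         beta0 = beta0, beta_metric = beta_metric, beta_sib = beta_sib,
         episode_duration_days = as.integer(episode_duration_days),
         gap_days = as.integer(gap_days),
         diary_missing_prob = diary_missing_prob,
         follow_up_days = as.integer(follow_up_days),
         locus = locus,
         prob_older_siblings = prob_older_siblings,
         seed = as.integer(seed)),
    class = "cohort_scenario")
}

# Vectorized batch of rearrangement draws; returns data.frame of sequences
# and their V/J names. Used unseeded inside an active RNG stream.
draw_rearrangements <- function(model, m) {
  nv <- nrow(model$v_segments)
  nj <- nrow(model$j_segments)
  vi <- sample.int(nv, m, replace = TRUE, prob = model$v_segments$prob)
  ji <- sample.int(nj, m, replace = TRUE, prob = model$j_segments$prob)
  tv <- sample.int(length(model$v_trim_probs), m, replace = TRUE,
                   prob = model$v_trim_probs) - 1L
  tj <- sample.int(length(model$j_trim_probs), m, replace = TRUE,
                   prob = model$j_trim_probs) - 1L
  li <- sample.int(length(model$insertion_length_probs), m, replace = TRUE,
                   prob = model$insertion_length_probs) - 1L
  total_bases <- sum(li)
  ins <- rep("", m)
  if (total_bases > 0L) {
    bases <- sample(c("A", "C", "G", "T"), total_bases, replace = TRUE,
                    prob = model$insertion_base_probs)
    grp <- factor(rep(seq_len(m), li), levels = seq_len(m))
    ins <- unname(vapply(split(bases, grp), paste0, character(1),
                         collapse = ""))
  }
  vseq <- model$v_segments$seq[vi]
  jseq <- model$j_segments$seq[ji]
  vpiece <- substr(vseq, 1L, pmax(0L, nchar(vseq) - tv))
  jpiece <- substr(jseq, pmin(nchar(jseq) + 1L, tj + 1L), nchar(jseq))
  data.frame(cdr3_nt = paste0(vpiece, ins, jpiece),
             v_gene = model$v_segments$name[vi],
             j_gene = model$j_segments$name[ji],
             stringsAsFactors = FALSE)
}

# Draw n distinct rearrangements, in frame and stop-free when
# productive = TRUE, out of frame when FALSE.
draw_distinct_clones <- function(model, n, productive = TRUE,
                                 exclude = character(0),
                                 max_batches = 200L) {
  found <- data.frame(cdr3_nt = character(0), v_gene = character(0),
                      j_gene = character(0), stringsAsFactors = FALSE)
  for (b in seq_len(max_batches)) {
    batch <- draw_rearrangements(model, max(1000L, 4L * n))
    aa <- translate_nt(batch$cdr3_nt)
    ok <- if (productive) {
      nchar(aa) > 0L & !grepl("*", aa, fixed = TRUE)
    } else {
      nchar(aa) == 0L
    }
    batch <- batch[ok, , drop = FALSE]
    batch <- batch[!duplicated(batch$cdr3_nt), , drop = FALSE]
    batch <- batch[!batch$cdr3_nt %in% c(found$cdr3_nt, exclude), ,
                   drop = FALSE]
    found <- rbind(found, batch)
    if (nrow(found) >= n) return(utils::head(found, n))
  }
  stop(sprintf(
    "could only draw %d of %d distinct clones; the model's sequence space is too small",
    nrow(found), n), call. = FALSE)
}

#' Simulate one repertoire with known ground truth
#'
#' Clone frequencies are drawn from a symmetric Dirichlet with
#' concentration `clone_concentration * exp(z)`, read counts from a
#' multinomial at `reads_per_subject`, and CDR3 sequences from the forward
#' sampler of [default_model()] (so every simulated sequence has a
#' computable Pgen). Productive clones are in frame and stop-free; a small
#' fraction of out-of-frame, non-productive clones is injected. For IGH, a
#' `shm_mutated_fraction` of clones gets germline identity uniform on
#' \[90, 98), the rest 100.
#'
#' @param scenario a [cohort_scenario()].
#' @param subject_seed integer seed; fixed seed gives an identical
#'   repertoire.
#' @param z latent diversity trait (0 = cohort average).
#' @param subject_id identifier for the repertoire.
#' @return A [repertoire()]; `attr(, "truth")` holds the generating
#'   frequencies, the true evenness of the frequency vector, and `alpha`.
#' @export
simulate_repertoire <- function(scenario, subject_seed, z = 0,
                                subject_id = "sim") {
  stopifnot(inherits(scenario, "cohort_scenario"))
  model <- default_model(scenario$v_gene_probs)
  with_seed(subject_seed, {
    alpha <- scenario$clone_concentration * exp(z)
    n <- scenario$n_clones
    freqs <- stats::rgamma(n, shape = alpha)
    if (sum(freqs) == 0) freqs <- rep(1, n)  # extreme alpha underflow guard
    freqs <- freqs / sum(freqs)
    counts <- as.integer(stats::rmultinom(1, scenario$reads_per_subject,
                                          freqs))
    clones <- draw_distinct_clones(model, n, productive = TRUE)
    clones$read_count <- counts
    clones$productive <- TRUE

    n_np <- round(scenario$nonproductive_fraction * n)
    if (n_np > 0L) {
      np <- draw_distinct_clones(model, n_np, productive = FALSE,
                                 exclude = clones$cdr3_nt)
      np$read_count <- pmax(1L, stats::rpois(n_np,
        mean(counts[counts > 0])))
      np$productive <- FALSE
      clones <- rbind(clones, np)
    }

    clones$v_identity_pct <- 100
    if (scenario$locus == "IGH") {
      mut <- stats::runif(nrow(clones)) < scenario$shm_mutated_fraction
      clones$v_identity_pct[mut] <- stats::runif(sum(mut), 90, 98)
    }
    clones <- clones[clones$read_count > 0L, , drop = FALSE]
    rep <- repertoire(clones, subject_id = subject_id,
                      locus = scenario$locus)
    attr(rep, "truth") <- list(
      alpha = alpha, z = z,
      true_freqs = freqs,
      true_evenness = if (n > 1) {
        -sum(freqs * log2(freqs)) / log2(n)
      } else 1)
    rep
  })
}

# Place k episodes of length d in [0, horizon) with at least min_sep
# non-qualifying days between and after them; returns start days.
plant_episode_starts <- function(k, d, min_sep, horizon) {
  if (k == 0L) return(integer(0))
  occupied <- k * d + (k - 1L) * min_sep
  slack <- horizon - occupied
  if (slack < 0L) {
    stop(sprintf(
      "infeasible packing: %d episodes of %d days with separation %d exceed %d follow-up days",
      k, d, min_sep, horizon), call. = FALSE)
  }
  extra <- as.integer(stats::rmultinom(1, slack, rep(1, k + 1L)))
  starts <- integer(k)
  pos <- extra[1]
  for (i in seq_len(k)) {
    starts[i] <- pos
    pos <- pos + d + min_sep + extra[i + 1L]
  }
  starts
}

#' Simulate a full cohort: repertoires, diaries, covariates and truth
#'
#' End-to-end generator for the whole pipeline. Per subject: a latent
#' diversity trait `z ~ N(0, 1)` drives both the repertoire's Dirichlet
#' concentration and (through `beta_metric`) the infection rate; the
#' cumulative episode count is Poisson with log-rate
#' `beta0 + beta_metric * z + beta_sib * older_siblings`. Episodes of fixed
#' duration are planted uniformly at random with separation greater than
#' `gap_days`, so episode calling at that gap recovers them exactly when no
#' diary days are missing. The first day of each episode carries one
#' A-symptom (fever) and the remaining days two B-symptoms (dry cough,
#' runny/blocked nose), exercising both halves of the ARI day rule. Diary
#' days are then dropped i.i.d. with probability `diary_missing_prob`.
#'
#' @param scenario a [cohort_scenario()].
#' @return List with `repertoires` (named list), `diaries` (named list),
#'   `covariates` (data.frame: subject_id, older_siblings, sex,
#'   birth_mode), and `truth` (betas, per-subject latent variables and
#'   planted episode tables).
#' @export
simulate_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  n <- scenario$n_subjects
  ids <- sprintf("S%03d", seq_len(n))
  with_seed(scenario$seed, {
    z <- stats::rnorm(n)
    sib <- stats::runif(n) < scenario$prob_older_siblings
    sex <- sample(c("female", "male"), n, replace = TRUE)
    birth_mode <- sample(c("vaginal", "c_section"), n, replace = TRUE,
                         prob = c(0.77, 0.23))
    subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
    lambda <- exp(scenario$beta0 + scenario$beta_metric * z +
                    scenario$beta_sib * sib)
    n_epi <- stats::rpois(n, lambda)

    diaries <- vector("list", n)
    planted <- vector("list", n)
    d <- scenario$episode_duration_days
    min_sep <- scenario$gap_days + 1L
    horizon <- scenario$follow_up_days
    for (i in seq_len(n)) {
      starts <- plant_episode_starts(n_epi[i], d, min_sep, horizon)
      planted[[i]] <- data.frame(start_day = starts,
                                 end_day = starts + d - 1L,
                                 n_symptom_days = rep(d, length(starts)))
      days <- data.frame(day = 0:(horizon - 1L), recorded = TRUE)
      for (s in c(a_symptoms(), b_symptoms())) days[[s]] <- FALSE
      for (s0 in starts) {
        days$fever[days$day == s0] <- TRUE
        if (d > 1L) {
          rest <- days$day > s0 & days$day <= s0 + d - 1L
          days$dry_cough[rest] <- TRUE
          days$runny_blocked_nose[rest] <- TRUE
        }
      }
      miss <- stats::runif(horizon) < scenario$diary_missing_prob
      days$recorded[miss] <- FALSE
      for (s in c(a_symptoms(), b_symptoms())) days[[s]][miss] <- FALSE
      diaries[[i]] <- symptom_diary(days, subject_id = ids[i])
    }

    repertoires <- lapply(seq_len(n), function(i) {
      simulate_repertoire(scenario, subject_seeds[i], z = z[i],
                          subject_id = ids[i])
    })
    names(repertoires) <- ids
    names(diaries) <- ids
    names(planted) <- ids

    list(repertoires = repertoires,
         diaries = diaries,
         covariates = data.frame(subject_id = ids,
                                 older_siblings = sib,
                                 sex = sex,
                                 birth_mode = birth_mode,
                                 stringsAsFactors = FALSE),
         truth = list(
           betas = c(beta0 = scenario$beta0,
                     beta_metric = scenario$beta_metric,
                     beta_sib = scenario$beta_sib),
           subjects = data.frame(subject_id = ids, z = z,
                                 older_siblings = sib,
                                 lambda = lambda, n_episodes = n_epi,
                                 alpha = scenario$clone_concentration * exp(z),
                                 stringsAsFactors = FALSE),
           episodes = planted))
  })
}

#' Simulate a regression-calibration cohort table
#'
#' Lightweight generator for validating the association fits without
#' simulating repertoires: the metric column is the latent trait itself and
#' cumulative counts follow the same Poisson log-rate model, episodes
#' assigned uniformly across the four years so each interval's expected
#' count is proportional to its length.
#'
#' @param n subjects.
#' @param beta0,beta_metric,beta_sib generating coefficients
#'   (cumulative count at year 4 has log-mean
#'   `beta0 + beta_metric * z + beta_sib * sib`).
#' @param prob_sib probability of older siblings.
#' @param seed integer seed.
#' @return data.frame with columns `subject_id`, `metric`,
#'   `older_siblings`, `ari_y1`..`ari_y4`, `completeness`.
#' @export
simulate_association_table <- function(n = 500L, beta0 = 3.4,
                                       beta_metric = -0.1, beta_sib = 0.15,
                                       prob_sib = 0.4, seed = 1L) {
  with_seed(seed, {
    z <- stats::rnorm(n)
    sib <- stats::runif(n) < prob_sib
    lambda <- exp(beta0 + beta_metric * z + beta_sib * sib)
    total <- stats::rpois(n, lambda)
    year_of <- lapply(total, function(k) sample.int(4L, k, replace = TRUE))
    cum <- t(vapply(year_of, function(y) {
      vapply(1:4, function(t) sum(y <= t), integer(1))
    }, integer(4)))
    out <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                      metric = z, older_siblings = sib,
                      stringsAsFactors = FALSE)
    out$ari_y1 <- cum[, 1]; out$ari_y2 <- cum[, 2]
    out$ari_y3 <- cum[, 3]; out$ari_y4 <- cum[, 4]
    out$completeness <- 1
    out
  })
}
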