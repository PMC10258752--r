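test_that("read_clonotype_table parses AIRR TSVs and merges duplicate CDR3s", {
  path <- write_fixture_tsv(c(
    "junction\tjunction_aa\tv_call\tj_call\tduplicate_count\tproductive\tv_identity",
    "TGTGCCAGC\tCAS\tTRBV05\tTRBJ01\t10\tTRUE\t100",
    "TGTGCCAGT\tCAS\tTRBV06\tTRBJ01\t4\tTRUE\t99.5",
    "TGTGCCACC\tCAT\tTRBV19\tTRBJ02\t1\tFALSE\t100"))
  rep <- read_clonotype_table(path, locus = "TRB", subject_id = "S1")
  expect_s3_class(rep, "repertoire")
  expect_equal(nrow(rep$clonotypes), 3L)
  expect_equal(rep$total_reads, 15L)
  expect_equal(rep$subject_id, "S1")

  # duplicate cdr3_nt rows merge by summing counts; majority V call wins,
  # ties broken lexicographically
  path2 <- write_fixture_tsv(c(
    "junction\tv_call\tj_call\tduplicate_count\tproductive",
    "TGTGCCAGC\tTRBV09\tTRBJ01\t5\tTRUE",
    "TGTGCCAGC\tTRBV02\tTRBJ01\t7\tTRUE",
    "TGTGCCAGC\tTRBV01\tTRBJ01\t7\tTRUE"))
  rep2 <- read_clonotype_table(path2, locus = "TRB")
  expect_equal(nrow(rep2$clonotypes), 1L)
  expect_equal(rep2$clonotypes$read_count, 19L)
  expect_equal(rep2$clonotypes$v_gene, "TRBV01")  # 7-read tie: lexicographic
})

test_that("read_clonotype_table reports format and parse errors precisely", {
  no_count <- write_fixture_tsv(c(
    "junction\tv_call\tj_call\tproductive",
    "TGTGCC\tV1\tJ1\tTRUE"))
  expect_error(read_clonotype_table(no_count), "duplicate_count")

  bad_count <- write_fixture_tsv(c(
    "junction\tv_call\tj_call\tduplicate_count\tproductive",
    "TGTGCC\tV1\tJ1\t3\tTRUE",
    "TGTGCA\tV1\tJ1\tmany\tTRUE"))
  expect_error(read_clonotype_table(bad_count), "row 2")
})

test_that("column_map override supports non-AIRR headers", {
  path <- write_fixture_tsv(c(
    "nSeqCDR3\tbestVGene\tbestJGene\tcloneCount\tisProductive",
    "TGTGCCAGC\tV5\tJ1\t6\tTRUE"))
  rep <- read_clonotype_table(path, column_map = c(
    cdr3_nt = "nSeqCDR3", v_gene = "bestVGene", j_gene = "bestJGene",
    read_count = "cloneCount", productive = "isProductive"))
  expect_equal(rep$clonotypes$v_gene, "V5")
  expect_equal(rep$total_reads, 6L)
})

test_that("filter_repertoire drops sub-threshold and non-productive clones", {
  rep <- toy_repertoire(c(1, 2, 5))
  filtered <- filter_repertoire(rep)
  expect_setequal(filtered$clonotypes$read_count, c(2L, 5L))
  expect_equal(filtered$total_reads, 7L)
  expect_equal(rep$total_reads, 8L)  # input untouched

  rep_np <- toy_repertoire(c(100, 10), productive = c(FALSE, TRUE))
  expect_equal(filter_repertoire(rep_np)$clonotypes$read_count, 10L)
  expect_equal(nrow(filter_repertoire(rep_np, productive_only = FALSE)$clonotypes),
               2L)

  # min_count = 1 with all-productive input is the identity
  expect_equal(filter_repertoire(rep, min_count = 1)$clonotypes,
               rep$clonotypes)
  expect_error(filter_repertoire(rep, min_count = 0), "min_count")
})

test_that("filter_repertoire is idempotent and subsets counts", {
  set.seed(11)
  for (i in 1:10) {
    rep <- toy_repertoire(sample(1:50, 20),
                          productive = sample(c(TRUE, FALSE), 20, TRUE))
    f1 <- filter_repertoire(rep)
    f2 <- filter_repertoire(f1)
    expect_identical(f1$clonotypes, f2$clonotypes)
    expect_true(all(f1$clonotypes$cdr3_nt %in% rep$clonotypes$cdr3_nt))
  }
})

test_that("downsample_reads conserves totals and respects bounds", {
  one <- toy_repertoire(1000)
  d <- downsample_reads(one, 100, seed = 1)
  expect_equal(d$clonotypes$read_count, 100L)
  expect_equal(d$normalized_to, 100L)

  rep <- toy_repertoire(c(40, 30, 20, 10))
  full <- downsample_reads(rep, 100, seed = 1)
  expect_setequal(full$clonotypes$read_count, rep$clonotypes$read_count)

  for (s in 1:20) {
    d <- downsample_reads(rep, 37, seed = s)
    expect_identical(d$total_reads, 37L)
    expect_lte(nrow(d$clonotypes), nrow(rep$clonotypes))
    orig <- rep$clonotypes$read_count[match(d$clonotypes$cdr3_nt,
                                            rep$clonotypes$cdr3_nt)]
    expect_true(all(d$clonotypes$read_count <= orig))
  }

  expect_identical(downsample_reads(rep, 37, seed = 5)$clonotypes,
                   downsample_reads(rep, 37, seed = 5)$clonotypes)
  expect_error(downsample_reads(rep, 101, seed = 1), "100.*101|101.*100")
})

test_that("downsample_reads matches the hypergeometric expectation", {
  # two clones 9000/1000, target 1000: sampled count of clone 1 has mean
  # 900 and variance n*p*(1-p)*fpc (finite population correction)
  rep <- repertoire(data.frame(cdr3_nt = c("AAAA", "CCCC"),
                               read_count = c(9000L, 1000L)),
                    "S1", "TRB")
  n_seeds <- 200
  draws <- vapply(seq_len(n_seeds), function(s) {
    d <- downsample_reads(rep, 1000, seed = s)
    d$clonotypes$read_count[d$clonotypes$cdr3_nt == "AAAA"]
  }, numeric(1))
  mu <- 1000 * 0.9
  v <- 1000 * 0.9 * 0.1 * (10000 - 1000) / (10000 - 1)
  se <- sqrt(v / n_seeds)
  expect_lt(abs(mean(draws) - mu), 3 * se)
})

test_that("read -> write -> read round-trip preserves every field", {
  rep <- toy_repertoire(c(12, 5, 3), v_identity = c(100, 97.9, 98),
                        v_gene = c("V1", "V2", "V3"),
                        productive = c(TRUE, TRUE, FALSE))
  rep$clonotypes$pgen <- c(1.2345678912345e-09, 0.5, NA)
  path <- tempfile(fileext = ".tsv")
  write_clonotype_table(rep, path)
  back <- read_clonotype_table(path, locus = "TRB",
                               subject_id = rep$subject_id)
  back$clonotypes$pgen <- as.numeric(
    utils::read.delim(path)[["pgen"]][match(back$clonotypes$cdr3_nt,
                                            utils::read.delim(path)[["junction"]])])
  ord <- match(rep$clonotypes$cdr3_nt, back$clonotypes$cdr3_nt)
  expect_equal(back$clonotypes[ord, ], rep$clonotypes,
               ignore_attr = "row.names")
  expect_equal(back$total_reads, rep$total_reads)
})
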