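test_that("category distributions carry exact counts and half-up percentages", {
  d <- category_distribution(c(apathy_sadness = 1), "tiny")
  expect_equal(d$percent[["apathy_sadness"]], 100)
  expect_error(category_distribution(c(apathy_sadness = 0), "none"), "zero")

  labs <- stats::setNames(c(rep("etc", 3), rep("apathy_sadness", 5)),
                          sprintf("u%d", 1:8))
  grp <- stats::setNames(rep(c("Eastern", "Western"), each = 4),
                         sprintf("u%d", 1:8))
  sh <- category_shares(labs, grp)
  expect_equal(sh$Eastern$counts[["etc"]], 3)
  expect_equal(sh$Eastern$percent[["etc"]], 75)
  expect_equal(sh$Western$counts[["apathy_sadness"]], 4)

  # half-up rounding at the second decimal: 1/8 = 12.5 -> 12.5; 1/3 -> 33.33
  d2 <- category_distribution(c(etc = 1, apathy_sadness = 2), "r")
  expect_equal(d2$percent[["etc"]], 33.33)
  expect_equal(d2$percent[["apathy_sadness"]], 66.67)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-0.125, 2), -0.13)

  # percentages sum to ~100 after rounding on random distributions
  set.seed(14)
  for (i in 1:10) {
    counts <- stats::setNames(rpois(8, 40) + 1, cats8)
    tot <- sum(category_distribution(counts, "x")$percent)
    expect_gte(tot, 99.96); expect_lte(tot, 100.04)
  }
})

test_that("per-category chi-square matches the manual Pearson oracle and chisq.test", {
  set.seed(8)
  for (i in 1:10) {
    ca <- stats::setNames(rpois(8, 50) + 5, cats8)
    cb <- stats::setNames(rpois(8, 70) + 5, cats8)
    da <- category_distribution(ca, "A"); db <- category_distribution(cb, "B")
    res <- per_category_chi_square(da, db)
    for (k in seq_len(8)) {
      cat <- res$category[k]
      oracle <- chisq_2x2_oracle(ca[[cat]], da$total, cb[[cat]], db$total)
      expect_equal(res$statistic[k], oracle, tolerance = 1e-9)
      ref <- suppressWarnings(chisq.test(
        matrix(c(ca[[cat]], da$total - ca[[cat]],
                 cb[[cat]], db$total - cb[[cat]]), 2, byrow = TRUE),
        correct = FALSE))
      expect_equal(res$statistic[k], unname(ref$statistic), tolerance = 1e-9)
      expect_equal(res$p[k], ref$p.value, tolerance = 1e-9)
    }
  }

  # null case and group-order symmetry
  d1 <- category_distribution(stats::setNames(rep(10, 8), cats8), "A")
  d2 <- category_distribution(stats::setNames(rep(30, 8), cats8), "B")
  res0 <- per_category_chi_square(d1, d2)
  expect_equal(res0$statistic, rep(0, 8))
  expect_equal(res0$p, rep(1, 8))
  ca <- stats::setNames(c(10, rep(90 / 7, 7)), cats8)
  expect_equal(per_category_chi_square(d1, d2)$statistic,
               per_category_chi_square(d2, d1)$statistic)

  # tiny expected counts are flagged unreliable
  small_a <- category_distribution(stats::setNames(c(1, rep(20, 7)), cats8), "A")
  small_b <- category_distribution(stats::setNames(c(0, rep(20, 7)), cats8), "B")
  expect_true(per_category_chi_square(small_a, small_b)$unreliable[1])
})

test_that("planted mixture differences surface as the smallest chi-square p-values", {
  base <- stats::setNames(rep(0.1, 8), cats8)
  east <- base; west <- base
  east[["apathy_sadness"]] <- 0.35; east[["dysfunctional_thoughts"]] <- 0.05
  west[["apathy_sadness"]] <- 0.05; west[["dysfunctional_thoughts"]] <- 0.35
  east[["etc"]] <- 1 - sum(east[names(east) != "etc"])
  west[["etc"]] <- 1 - sum(west[names(west) != "etc"])
  for (seed in 1:5) {
    cfg <- generator_config(n_users_per_region = 1200,
                            utterances_per_user = list(mean = 1, dispersion = 1),
                            category_mixture = list(Eastern = east,
                                                    Western = west),
                            seed = seed)
    syn <- generate_corpus(cfg)
    groups <- stats::setNames(syn$records$region, syn$records$utterance_id)
    sh <- category_shares(syn$true_labels, groups)
    res <- per_category_chi_square(sh$Eastern, sh$Western)
    top2 <- res$category[order(res$p)][1:2]
    expect_setequal(top2, c("apathy_sadness", "dysfunctional_thoughts"))
  }
})

test_that("reference comparison reports printed shares and leaves gaps as NA", {
  ref <- twitter_reference()
  expect_equal(ref$categories$apathy_sadness$percent, 7.53)
  expect_equal(ref$categories$dysfunctional_thoughts$percent, 25.17)
  expect_equal(ref$categories$social_struggles$percent, 21.89)
  expect_true(isTRUE(ref$categories$hiding_behind_mask$discrepant))

  counts <- stats::setNames(c(14385, 0, 11705, 5870, 74045, 0, 11451, 27101),
                            cats8)
  dist <- category_distribution(counts, "chatbot", total = 148590)
  cmp <- compare_to_reference(dist, ref)
  apathy <- cmp[cmp$category == "apathy_sadness", ]
  expect_equal(apathy$percent, 49.83)
  expect_equal(apathy$difference, 49.83 - 7.53)
  expect_true(is.na(cmp$ref_percent[cmp$category == "etc"]))
  # comparing to an identical reference yields zero differences
  self_ref <- list(categories = lapply(as.list(dist$percent),
                                       function(p) list(percent = p)))
  expect_equal(compare_to_reference(dist, self_ref)$difference, rep(0, 8))
})

test_that("reports are deterministic and degrade gracefully when empty", {
  empty <- render_report(list(), seed = 1)
  expect_true(any(grepl("no results", empty)))

  res <- list(chi_square = data.frame(category = "etc", statistic = 1,
                                      df = 1, p = 0.3, unreliable = FALSE))
  stem <- file.path(tempdir(), "rep_test")
  r1 <- render_report(res, seed = 5, config = list(a = 1), path = stem)
  expect_true(file.exists(paste0(stem, ".md")))
  expect_true(file.exists(paste0(stem, ".json")))
  r2 <- render_report(res, seed = 5, config = list(a = 1), path = stem)
  expect_identical(r1, r2)
  # the header names the seed and a config hash
  expect_true(any(grepl("seed: 5", r1)))
  expect_true(any(grepl("config hash: [0-9a-f]+", r1)))
})
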