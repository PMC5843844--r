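test_that("marginal means equal brute-force group averages", {
  tab <- random_response_table(seed = 31)
  mm <- marginal_means(tab, "R848")
  for (i in seq_len(nrow(mm))) {
    expect_equal(mm$mean[i],
                 mean(tab$response[tab$R848 == mm$level[i]]))
  }
  ## grand mean of marginals equals grand mean of table (balanced)
  expect_equal(mean(mm$mean), mean(tab$response))

  const <- tab; const$response <- 7.5
  mc <- marginal_means(const, "IL21")
  expect_true(all(mc$mean == 7.5))

  ## pure main effect: response = level index of IL-21
  pure <- tab
  pure$response <- match(pure$IL21, c("10", "50", "100")) - 1
  mp <- marginal_means(pure, "IL21")
  expect_equal(mp$mean, c(0, 1, 2))

  expect_error(marginal_means(tab, "IL9"), "absent")
  expect_error(marginal_means(tab[0, ], "IL21"), "empty")
})

test_that("every sum of squares matches the independent aov oracle", {
  for (seed in c(101, 202, 303)) {
    tab <- random_response_table(seed)
    dec <- anova_decompose(tab)
    oracle <- aov_ss_oracle(tab)
    for (term in names(oracle$ss)) {
      mine <- dec$ss[dec$term == term]
      if (term == "Residuals") mine <- dec$ss[dec$term == "residual"]
      expect_equal(unname(mine), unname(oracle$ss[[term]]), tolerance = 1e-9,
                   label = paste("SS", term, "seed", seed))
    }
    ## p-values against the F-distribution oracle through aov
    for (term in setdiff(names(oracle$p), "Residuals")) {
      p_mine <- dec$p[dec$term == term]
      if (!is.na(oracle$p[[term]]))
        expect_equal(unname(p_mine), unname(oracle$p[[term]]),
                     tolerance = 1e-10)
    }
  }
})

test_that("SS additivity and factor-order invariance hold on balanced data", {
  tab <- random_response_table(seed = 77)
  dec <- anova_decompose(tab)
  expect_equal(sum(dec$ss), attr(dec, "ss_total"),
               tolerance = 1e-9)
  ## permute the factor columns: same decomposition, different row order
  perm <- tab[, c("condition_id", "CD40", "R848", "CpG", "IL21",
                  "donor", "replicate", "isotype", "response")]
  dec2 <- anova_decompose(perm)
  key <- function(x) vapply(strsplit(x, ":"), function(p)
    paste(sort(p), collapse = ":"), "")
  m <- match(key(dec$term), key(dec2$term))
  expect_equal(dec$ss, dec2$ss[m], tolerance = 1e-9)
  expect_equal(dec$p, dec2$p[m], tolerance = 1e-9)
})

test_that("degenerate and single-source variance tables decompose correctly", {
  tab <- random_response_table(seed = 5)
  const <- tab; const$response <- 3
  dec <- anova_decompose(const)
  expect_true(attr(dec, "degenerate"))
  expect_equal(attr(dec, "ss_total"), 0)
  expect_true(all(is.na(dec$f)))
  rep0 <- sensitivity_indices(dec)
  expect_true(all(rep0$index == 0))
  expect_true(attr(rep0, "degenerate"))

  pure <- tab
  pure$response <- 10 * (match(pure$IL21, c("10", "50", "100")) - 1)
  decp <- anova_decompose(pure)
  expect_equal(decp$ss[decp$term == "IL21"], attr(decp, "ss_total"))
  expect_equal(sum(decp$ss[decp$term != "IL21"]), 0, tolerance = 1e-9)
  repp <- sensitivity_indices(decp)
  expect_equal(repp$index[repp$term == "IL21"], 1)
})

test_that("unbalanced tables are refused", {
  tab <- random_response_table(seed = 8)
  expect_error(anova_decompose(tab[-1, ]), "unbalanced")
})

test_that("equal-spread additive factors split the variance 50/50", {
  des <- enumerate_design(list(doe_factor("A", c("1", "2", "3")),
                               doe_factor("B", c("1", "2", "3"))))
  tab <- data.frame(des, donor = "d1", replicate = 1L,
                    response = as.numeric(des$A) + as.numeric(des$B))
  dec <- anova_decompose(tab, include_donor_block = FALSE)
  rep2 <- sensitivity_indices(dec)
  expect_equal(rep2$index[rep2$term == "A"], 0.5, tolerance = 1e-9)
  expect_equal(rep2$index[rep2$term == "B"], 0.5, tolerance = 1e-9)
  expect_true(all(rep2$index >= 0 & rep2$index <= 1))
  ## no replication: F/p undefined but indices remain valid
  expect_true(all(is.na(rep2$f)))
})

test_that("optimal-condition selection follows significance and dose rules", {
  factors <- mbc_expansion_factors()
  des <- enumerate_design(factors)
  tab <- simulate_doe_response(des, doe_effects_scenario(seed = 3))
  dec <- anova_decompose(tab)
  rep3 <- sensitivity_indices(dec)
  marg <- setNames(lapply(factors, function(f) marginal_means(tab, f$name)),
                   vapply(factors, `[[`, "", "name"))
  opt <- select_optimal(rep3, marg, factors)
  expect_equal(setNames(opt$level, opt$factor),
               c(IL21 = "100", CpG = "0", R848 = "0.5", CD40 = "1:1"))
  expect_equal(opt$rationale[opt$factor == "CpG"], "default-lowest")

  ## all-null: every factor drops to its lowest dose
  null_tab <- simulate_doe_response(des, doe_sim_params(
    noise_sd = 1, donor_offsets = c(d1 = 0, d2 = 0, d3 = 0), seed = 4))
  dn <- anova_decompose(null_tab)
  rn <- sensitivity_indices(dn)
  margn <- setNames(lapply(factors, function(f) marginal_means(null_tab, f$name)),
                    vapply(factors, `[[`, "", "name"))
  ## force non-significance deterministically for the rule check
  rn$p[rn$order %in% 1L] <- 0.9
  optn <- select_optimal(rn, margn, factors)
  expect_equal(optn$level,
               vapply(factors, function(f) f$levels[1], ""))

  ## exact tie in marginal means breaks toward the lower dose
  rtie <- rn
  rtie$p[rtie$term == "IL21"] <- 0.001
  mtie <- margn
  mtie$IL21$mean <- c(5, 9, 9)  # levels 50 and 100 tied
  optt <- select_optimal(rtie, mtie, factors)
  expect_equal(optt$level[optt$factor == "IL21"], "50")
})

test_that("two-way ANOVA with Tukey HSD matches the studentized-range oracle", {
  set.seed(99)
  d <- expand.grid(g = c("a", "b", "c"), t = c("t1", "t2"),
                   rep = 1:6, stringsAsFactors = FALSE)
  d$response <- rnorm(nrow(d))
  ## identical groups: nothing significant
  res <- two_way_anova_tukey(d, "response", "g", "t")
  expect_true(all(res$tukey$g$p_adj > 0.05))

  ## one group shifted by 100x pooled SD
  d2 <- d
  d2$response[d2$g == "c"] <- d2$response[d2$g == "c"] + 100
  res2 <- two_way_anova_tukey(d2, "response", "g", "t")
  pc <- res2$tukey$g$p_adj[grepl("c", res2$tukey$g$comparison)]
  expect_true(all(pc < 1e-6))

  ## numerical oracle: recompute one adjusted p from ptukey
  fit <- stats::aov(response ~ factor(g) * factor(t), data = d)
  mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  dfres <- summary(fit)[[1]]["Residuals", "Df"]
  ni <- sum(d$g == "a")
  diff_ab <- mean(d$response[d$g == "b"]) - mean(d$response[d$g == "a"])
  q <- abs(diff_ab) / sqrt(mse / ni)
  p_oracle <- stats::ptukey(q, nmeans = 3, df = dfres, lower.tail = FALSE)
  p_mine <- res$tukey$g$p_adj[res$tukey$g$comparison == "b-a"]
  expect_equal(p_mine, p_oracle, tolerance = 1e-8)

  expect_error(two_way_anova_tukey(d[d$rep == 1 & d$t == "t1", ],
                                   "response", "g", "t"),
               ">= 2")
})
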