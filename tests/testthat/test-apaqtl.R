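# Quantile normalization, confounder removal, cis scan, permutation FDR, pi1.

test_that("inverse-normal transform maps ranks to standard-normal quantiles", {
  m <- matrix(c(5, 1, 3), ncol = 1)
  got <- quantile_normalize(m)[, 1]
  expect_equal(got, qnorm(c(2.5, 0.5, 1.5) / 3), tolerance = 1e-10)
  expect_equal(got, c(0.9674, -0.9674, 0), tolerance = 1e-4)
  # ties get averaged ranks
  got2 <- quantile_normalize(matrix(c(2, 2, 5), ncol = 1))[, 1]
  expect_equal(got2, qnorm(c(1, 1, 2.5) / 3), tolerance = 1e-10)
  expect_equal(got2[1], got2[2])
  # rank invariance under strictly monotone transforms
  set.seed(19)
  x <- matrix(rgamma(40, 2), ncol = 2)
  expect_equal(quantile_normalize(x), quantile_normalize(exp(x)))
  expect_warning(quantile_normalize(cbind(x, 1)), "constant")
})

test_that("transformed sites look normal for moderate sample sizes", {
  set.seed(23)
  pass <- replicate(40, {
    x <- matrix(rbeta(30, 0.4, 2), ncol = 1)   # heavily skewed input
    shapiro.test(quantile_normalize(x)[, 1])$p.value > 0.01
  })
  expect_gte(mean(pass), 0.95)
})

test_that("PC removal strips a planted batch effect and keeps orthogonal signal", {
  set.seed(29)
  n <- 60; p <- 30
  batch <- rnorm(n)
  mat <- outer(batch, rnorm(p, 2, 0.3)) + matrix(rnorm(n * p, 0, 0.5), n)
  res <- remove_confounders(mat, n_pcs = 1)
  cors <- abs(cor(batch, res))
  expect_lt(max(cors), 0.05)
  expect_equal(remove_confounders(mat, 0), mat)
  expect_error(remove_confounders(mat, 60), "samples")
})

test_that("cis scan recovers a perfect association and respects the window", {
  set.seed(37)
  n <- 50
  g <- rbinom(n, 2, 0.4)
  dosage <- cbind(v1 = g, v2 = rbinom(n, 2, 0.3), v3 = rbinom(n, 2, 0.3))
  rownames(dosage) <- sprintf("S%02d", 1:n)
  geno <- list(dosage = dosage,
               variants = data.frame(variant_id = c("v1", "v2", "v3"),
                                     chrom = "chrS",
                                     position = c(1000L, 20000L, 26001L)))
  mat <- matrix(as.numeric(g), ncol = 1,
                dimnames = list(rownames(dosage), "s1"))
  meta <- data.frame(site_id = "s1", chrom = "chrS", position = 1000L)
  res <- cis_scan(mat, meta, geno, window = 25000L, maf_min = 0.05)
  # v3 sits at distance 25001 > 25000 and is excluded
  expect_setequal(res$variant_id, c("v1", "v2"))
  lead <- res[res$variant_id == "v1", ]
  expect_equal(lead$slope, 1, tolerance = 1e-9)
  expect_lt(lead$p, 1e-30)
})

test_that("nominal p-values are uniform under the null", {
  cfg <- sim_config(seed = 43, n_samples = 60, planted_qtl_fraction = 0)
  co <- simulate_qtl_cohort(cfg, n_sites = 50)
  rz <- remove_confounders(quantile_normalize(co$pau), 4)
  nom <- cis_scan(rz, co$site_meta, co$geno, window = 25000L)
  expect_gt(nrow(nom), 400)
  ks <- suppressWarnings(ks.test(nom$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("permutation p-values have the floor implied by n_perm", {
  cfg <- sim_config(seed = 47, n_samples = 30, planted_qtl_fraction = 1,
                    qtl_effect_r2 = 0.5)
  co <- simulate_qtl_cohort(cfg, n_sites = 5)
  rz <- quantile_normalize(co$pau)
  res <- lead_permutation_fdr(rz, co$site_meta, co$geno, n_perm = 1L,
                              seed = 3)
  expect_true(all(res$perm_p %in% c(0.5, 1)))
  res2 <- lead_permutation_fdr(rz, co$site_meta, co$geno, n_perm = 100L,
                               seed = 3)
  expect_true(all(res2$perm_p >= 1 / 101))
})

test_that("strong planted effects are detected at FDR 10%", {
  detected <- 0L; total <- 0L
  for (rep in 1:25) {
    cfg <- sim_config(seed = 600 + rep, n_samples = 60,
                      planted_qtl_fraction = 1, qtl_effect_r2 = 0.5)
    co <- simulate_qtl_cohort(cfg, n_sites = 4, maf_range = c(0.3, 0.3))
    rz <- quantile_normalize(co$pau)
    res <- lead_permutation_fdr(rz, co$site_meta, co$geno, n_perm = 300L,
                                fdr = 0.10, seed = 700 + rep)
    detected <- detected + sum(res$significant)
    total <- total + nrow(res)
  }
  expect_gte(detected / total, 0.95)
})

test_that("planted slopes are recovered with the right sign", {
  cfg <- sim_config(seed = 53, n_samples = 60, planted_qtl_fraction = 1,
                    qtl_effect_r2 = 0.2)
  co <- simulate_qtl_cohort(cfg, n_sites = 30, maf_range = c(0.3, 0.3))
  rz <- quantile_normalize(co$pau)
  nom <- cis_scan(rz, co$site_meta, co$geno)
  hits <- merge(nom, co$truth, by.x = c("site_id", "variant_id"),
                by.y = c("site_id", "variant"))
  expect_equal(nrow(hits), 30L)
  expect_gte(mean(hits$slope > 0), 0.9)   # planted beta > 0 on the logit scale
  # dosage-usage correlation near sqrt(R2)
  cors <- vapply(seq_len(nrow(co$truth)), function(i)
    cor(co$pau[, co$truth$site_id[i]],
        co$geno$dosage[, co$truth$variant[i]]), 0)
  expect_lt(abs(mean(cors) - sqrt(0.2)), 0.1)
})

test_that("pi1 recovers null, mixed and saturated sharing", {
  set.seed(59)
  expect_lt(pi1_sharing(runif(1000))$pi1, 0.05)
  expect_equal(pi1_sharing(rep(1e-8, 1000))$pi1, 1)
  expect_error(pi1_sharing(numeric(0)), "empty")
  expect_warning(pi1_sharing(runif(10)), "20")
  # monotone in the planted sharing fraction (averaged over replicates)
  fracs <- c(0, 0.25, 0.5, 0.75, 1)
  est <- vapply(fracs, function(f) {
    mean(replicate(10, {
      p <- c(rbeta(round(1000 * f), 0.1, 1), runif(round(1000 * (1 - f))))
      pi1_sharing(p)$pi1
    }))
  }, 0)
  expect_true(all(diff(est) > 0))
})
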