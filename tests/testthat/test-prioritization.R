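# fixed 10-sample fixture: gene GA amplified in 2 samples, z > 1 in 3
# (1 overlapping), gene GB unaltered
fixture_cna_z <- function() {
  samples <- paste0("s", 1:10)
  cna <- matrix(0L, 2, 10, dimnames = list(c("GA", "GB"), samples))
  cna["GA", 1:2] <- 2L
  z <- matrix(0, 2, 10, dimnames = list(c("GA", "GB"), samples))
  z["GA", c(2, 3, 4)] <- 1.5
  list(cna = cna, z = z)
}

test_that("alteration rate literally sums the two percentages", {
  f <- fixture_cna_z()
  prof <- alteration_profile(c("GA", "GB"), f$cna, f$z)
  expect_equal(prof$pct_amplified, c(20, 0))
  expect_equal(prof$pct_mrna_up, c(30, 0))
  expect_equal(prof$alteration_rate, c(50, 0)) # overlap double-counted
  # union mode counts altered samples once
  prof_u <- alteration_profile(c("GA", "GB"), f$cna, f$z, mode = "union")
  expect_equal(prof_u$alteration_rate, c(40, 0))
  expect_error(alteration_profile("GX", f$cna, f$z), "GX")
})

test_that("GL1 applies a strict threshold and ranks by rate", {
  f <- fixture_cna_z()
  expect_identical(build_gl1(c("GA", "GB"), f$cna, f$z)$symbols, "GA")
  expect_identical(build_gl1(c("GB", "GA"), f$cna, f$z,
                             threshold = 0)$symbols, "GA")
  expect_length(build_gl1(c("GA", "GB"), f$cna, f$z, threshold = 50), 0)
})

test_that("GL2 amplification arithmetic matches the 180-sample cohort", {
  samples <- paste0("m", 1:180)
  cna <- matrix(0L, 3, 180,
                dimnames = list(c("GA", "GB", "GC"), samples))
  cna["GA", 1:2] <- 2L  # 2/180 = 1.11% > 1  -> in
  cna["GB", 1] <- 2L    # 1/180 = 0.56%      -> out
  expect_identical(build_gl2(c("GA", "GB", "GC"), cna)$symbols, "GA")
  expect_length(build_gl2("GC", cna), 0)
})

test_that("GL3 requires a strict maximum in the basal subtype", {
  samples <- paste0("s", 1:10)
  cl <- make_clinical(samples,
                      PAM50 = c("Basal", "Basal", "LumA", "LumA", "LumB",
                                "LumB", "HER2E", "HER2E", "Normal-like",
                                "Normal-like"))
  expr <- matrix(1, 3, 10, dimnames = list(c("UNIF", "BHI", "TIE"), samples))
  expr["BHI", 1:2] <- 31      # log2 mean 5 in basal, 1 elsewhere
  expr["TIE", 1:4] <- 31      # exact tie between Basal and LumA
  gl3 <- build_gl3(c("UNIF", "BHI", "TIE"), expr, cl)
  expect_identical(gl3$symbols, "BHI")
  cl_missing <- cl; cl_missing$PAM50[cl_missing$PAM50 == "HER2E"] <- "LumA"
  expect_error(build_gl3("BHI", expr, cl_missing), "HER2E")
})

test_that("GL4 is one-sided towards TNBC enrichment", {
  set.seed(10)
  samples <- paste0("s", 1:40)
  tnbc <- samples[1:20]
  expr <- rbind(UP = c(2^(5 + rnorm(20, 1, 0.3)), 2^(5 + rnorm(20, 0, 0.3))),
                DOWN = c(2^(5 + rnorm(20, -1, 0.3)), 2^(5 + rnorm(20, 0, 0.3))),
                NULL1 = 2^(5 + rnorm(40, 0, 0.3)))
  colnames(expr) <- samples
  gl4 <- build_gl4(c("UP", "DOWN", "NULL1"), expr, tnbc)
  expect_true("UP" %in% gl4$symbols)
  expect_false("DOWN" %in% gl4$symbols) # wrong direction
  expect_error(build_gl4("UP", expr, samples), ">= 2 samples")
})

test_that("GL5 demands significance AND the poor-prognosis direction on both
          endpoints", {
  set.seed(20)
  n <- 120
  samples <- paste0("s", 1:n)
  x <- rnorm(n)
  # RISK: high expression doubles the hazard on both endpoints;
  # PROT: high expression is protective (direction gate must exclude it)
  rate_bad <- 0.02 * exp(log(4) * (x > median(x)))
  rate_good <- 0.02 * exp(-log(4) * (x > median(x)))
  cl <- make_clinical(samples,
                      OS_time = rexp(n, rate_bad), OS_event = 1,
                      DMFS_time = rexp(n, rate_bad), DMFS_event = 1)
  expr <- rbind(RISK = 2^(5 + x), PROT = 2^(5 + x))
  colnames(expr) <- samples
  cl_prot <- cl
  cl_prot$OS_time <- rexp(n, rate_good)
  cl_prot$DMFS_time <- rexp(n, rate_good)
  expect_identical(build_gl5("RISK", expr, cl)$symbols, "RISK")
  expect_length(build_gl5("PROT", expr, cl_prot), 0)
  cl_cens <- cl
  cl_cens$OS_event <- 0; cl_cens$DMFS_event <- 0
  expect_error(build_gl5("RISK", expr, cl_cens), "censored")
})

test_that("panel split is floor(n/2) most sensitive lines", {
  mk_panel <- function(ec50) {
    lines <- sprintf("L%02d", seq_along(ec50))
    expr <- matrix(rnorm(2 * length(ec50)), 2,
                   dimnames = list(c("GA", "GB"), lines))
    cell_line_panel(lines, stats::setNames(ec50, lines), expr)
  }
  s4 <- classify_panel(mk_panel(c(1, 2, 3, 4)))
  expect_identical(s4$ms, c("L01", "L02"))
  s2 <- classify_panel(mk_panel(c(9, 3)))
  expect_identical(s2$ms, "L02")
  expect_identical(s2$ls, "L01")
  s37 <- classify_panel(mk_panel(seq(0.5, 40, length.out = 37)))
  expect_equal(c(length(s37$ms), length(s37$ls)), c(18, 19))
})

test_that("GL6 selects genes over-expressed in less-sensitive lines only", {
  genes <- c("RES", "FLAT", "SENS")
  panel <- simulate_panel(panel_spec(genes, resistance_genes = "RES",
                                     n_lines = 37, seed = 3))
  panel$expr["FLAT", ] <- 5
  split <- classify_panel(panel)
  panel$expr["SENS", split$ms] <- panel$expr["SENS", split$ms] + 3
  gl6 <- build_gl6(genes, panel)
  expect_identical(gl6$symbols, "RES")
})

test_that("list builders are monotone in their thresholds", {
  co <- small_planted_cohort()
  tnbc <- select_tnbc(co$clinical)
  genes <- c(co$truth$planted_genes, "PTGS2")
  z <- zscore_matrix(co$expression[, tnbc])
  cna <- co$cna[, tnbc]
  prev <- character()
  for (th in c(40, 20, 10, 0)) {
    cur <- build_gl1(genes, cna, z, threshold = th)$symbols
    expect_true(all(prev %in% cur)) # relaxing never removes a gene
    prev <- cur
  }
  prev <- character()
  for (th in c(20, 5, 1, 0)) {
    cur <- build_gl2(genes, co$cna, threshold = th)$symbols
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("co-expression confirmation keeps marker-correlated genes", {
  co <- small_planted_cohort()
  tnbc <- select_tnbc(co$clinical)
  expr <- co$expression[, tnbc]
  genes <- c("PTGS2", co$truth$planted_genes[1:5], "G0001")
  coex <- coexpression_confirm(genes, expr, "PTGS2")
  expect_true("PTGS2" %in% coex$symbols) # marker vs itself: r = 1
  expect_gt(mean(co$truth$planted_genes[1:5] %in% coex$symbols), 0.6)
  # zero-variance gene fails with a warning
  expr2 <- rbind(expr, CONST = 5)
  expect_warning(res <- coexpression_confirm(c("CONST"), expr2, "PTGS2"),
                 "zero-variance")
  expect_length(res, 0)
})

test_that("the assembled prioritization result nests consistently", {
  co <- small_planted_cohort()
  tnbc <- select_tnbc(co$clinical)
  z <- zscore_matrix(co$expression[, tnbc])
  met <- simulate_cohort(cohort_spec(n_patients = 180, n_genes = 300,
                                     planted_genes = co$truth$planted_genes,
                                     planted_down_genes =
                                       co$truth$planted_down_genes,
                                     seed = 52))$cna
  panel <- simulate_panel(panel_spec(rownames(co$expression),
                                     resistance_genes =
                                       co$truth$planted_genes, seed = 53))
  res <- prioritize(co$truth$planted_genes, cna = co$cna[, tnbc], z = z,
                    expr = co$expression, clinical = co$clinical,
                    tnbc_ids = tnbc, cna_metastatic = met, panel = panel)
  for (gl in res$gene_lists)
    expect_true(all(res$intersection$symbols %in% gl$symbols))
  expect_true(all(res$coexpressed$symbols %in% res$intersection$symbols))
})
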