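# Stats table stub marking the given features significant.
stubStats <- function(ids, sig = rep(TRUE, length(ids))) {
  S4Vectors::DataFrame(feature_id = ids, n_control_used = 6L,
                       n_case_used = 7L, outliers_removed = "",
                       u_statistic = 1, p_value = 0.01, p_adjusted = 0.01,
                       log2_fc = 1, significant = sig)
}

test_that("merging keeps exactly the significant features of both layers", {
  prot <- toyLayer(nFeat = 80, seed = 1, layer = "protein",
                   nControl = 6, nCase = 9)
  met <- toyLayer(nFeat = 20, seed = 2, layer = "metabolite",
                  nControl = 6, nCase = 7)
  sigP <- rownames(prot)[1:73]
  sigM <- rownames(met)[1:16]
  merged <- mergeLayers(stubStats(rownames(prot),
                                  rownames(prot) %in% sigP),
                        stubStats(rownames(met),
                                  rownames(met) %in% sigM),
                        prot, met)
  expect_equal(ncol(merged$values), 89L)  # 73 proteins + 16 metabolites
  expect_equal(sum(merged$featureLayer == "protein"), 73L)
  expect_equal(sum(merged$featureLayer == "metabolite"), 16L)
  expect_equal(nrow(merged$values), 13L)  # shared samples only
})

test_that("metabolite columns are natural-log transformed, zeros become missing", {
  v <- matrix(exp(2), nrow = 1, ncol = 13,
              dimnames = list("M1", c(sprintf("C%02d", 1:6),
                                      sprintf("IVDH%02d", 1:7))))
  v[1, 1] <- 0
  met <- makeLayer(v, rep(c("control", "case"), c(6, 7)), "metabolite")
  prot <- toyLayer(nFeat = 3, seed = 3, nControl = 6, nCase = 7)
  merged <- mergeLayers(stubStats(rownames(prot)), stubStats("M1"),
                        prot, met)
  expect_true(is.na(merged$values["C01", "M1"]))
  expect_equal(unname(merged$values["C02", "M1"]), 2)
  # protein columns are untouched
  expect_equal(merged$values[, rownames(prot)],
               t(intensities(prot))[rownames(merged$values), ])
})

test_that("merging fails without shared samples and warns on empty layers", {
  protv <- matrix(1:4, 2, 2, dimnames = list(c("P1", "P2"), c("A1", "A2")))
  metv <- matrix(1:4, 2, 2, dimnames = list(c("M1", "M2"), c("B1", "B2")))
  prot <- makeLayer(protv, c("control", "case"))
  met <- makeLayer(metv, c("control", "case"), "metabolite")
  expect_error(mergeLayers(stubStats(c("P1", "P2")), stubStats(c("M1", "M2")),
                           prot, met), "share no samples")
  prot2 <- toyLayer(nFeat = 4, seed = 4, nControl = 6, nCase = 7)
  met2 <- toyLayer(nFeat = 4, seed = 5, layer = "metabolite",
                   nControl = 6, nCase = 7)
  expect_warning(mergeLayers(stubStats(rownames(prot2), rep(FALSE, 4)),
                             stubStats(rownames(met2)), prot2, met2),
                 "no significant protein")
})

test_that("train/test split sizes follow round-half-down of the ratio", {
  s13 <- paste0("S", 1:13)
  g13 <- rep(c("control", "case"), c(6, 7))
  sp <- splitTrainTest(s13, g13, 0.7, seed = 1)
  expect_length(sp$trainIds, 9L)
  expect_length(sp$testIds, 4L)

  s20 <- paste0("S", 1:20)
  g20 <- rep(c("control", "case"), each = 10)
  sp20 <- splitTrainTest(s20, g20, 0.7, seed = 1)
  expect_length(sp20$trainIds, 14L)
  expect_length(sp20$testIds, 6L)
})

test_that("the split is a stratified partition, deterministic under seed", {
  s <- paste0("S", 1:13)
  g <- setNames(rep(c("control", "case"), c(6, 7)), s)
  a <- splitTrainTest(s, g, 0.7, seed = 5)
  b <- splitTrainTest(s, g, 0.7, seed = 5)
  expect_identical(a, b)
  expect_setequal(c(a$trainIds, a$testIds), s)
  expect_length(intersect(a$trainIds, a$testIds), 0L)
  # both classes in both partitions
  for (part in a) expect_setequal(unique(unname(g[part])), c("control", "case"))
  # a different seed moves members but not sizes
  d <- splitTrainTest(s, g, 0.7, seed = 6)
  expect_length(d$trainIds, 9L)
  expect_false(identical(sort(a$trainIds), sort(d$trainIds)))
})

test_that("ratio 1 puts everything in training", {
  sp <- splitTrainTest(paste0("S", 1:5), rep(c("control", "case"), c(2, 3)),
                       ratio = 1, seed = 1)
  expect_length(sp$trainIds, 5L)
  expect_length(sp$testIds, 0L)
})

test_that("scaling is learned on training data with the n-1 denominator", {
  train <- matrix(c(1, 3), 2, 1, dimnames = list(c("a", "b"), "F1"))
  sc <- fitScaling(train)
  expect_equal(sc$mean, 2)
  expect_equal(sc$sd, sqrt(2))
  z <- applyScaling(train, sc)
  expect_equal(unname(z[, 1]), c(-1, 1) / sqrt(2))
  # test value equal to the training mean maps to 0
  expect_equal(as.numeric(applyScaling(matrix(2, 1, 1,
                                              dimnames = list("c", "F1")),
                                       sc)), 0)
})

test_that("constant columns are centred only and flagged", {
  train <- matrix(c(5, 5, 5, 1, 2, 3), 3, 2,
                  dimnames = list(NULL, c("const", "var")))
  sc <- fitScaling(train)
  expect_true(sc$constant[sc$feature == "const"])
  z <- applyScaling(train, sc)
  expect_equal(unname(z[, "const"]), c(0, 0, 0))
})

test_that("standardized training columns have mean 0 and sd 1", {
  withr::local_seed(8)
  train <- matrix(rnorm(60), 10, 6,
                  dimnames = list(NULL, paste0("F", 1:6)))
  z <- applyScaling(train, fitScaling(train))
  expect_true(all(abs(colMeans(z)) < 1e-9))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-9))
})

test_that("KNN imputation preserves observed values and handles degenerate k", {
  m <- matrix(rnorm(20), 4, 5, dimnames = list(paste0("s", 1:4),
                                               paste0("F", 1:5)))
  expect_identical(knnImpute(m, k = 2), structure(m, imputedZero = character()))

  m2 <- m
  m2[1, 3] <- NA
  filled <- knnImpute(m2, k = 10)  # k exceeds donors -> all-donor mean
  expect_equal(filled[1, 3], mean(m2[2:4, 3]))
  filled[1, 3] <- NA
  attr(filled, "imputedZero") <- NULL
  expect_identical(filled, m2)
})

test_that("KNN imputation matches a hand-computed nearest-neighbour fixture", {
  x <- matrix(c(0, 0,  NA,
                0, 0.1, 10,
                5, 5,   20), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("F1", "F2", "F3")))
  # distances from s1 on shared features: to s2 sqrt(mean(0, .01)) = 0.0707,
  # to s3 sqrt(mean(25, 25)) = 5 -> with k = 1 the donor is s2
  filled <- knnImpute(x, k = 1)
  expect_equal(filled["s1", "F3"], 10)
  # k = 2 averages both donors
  expect_equal(knnImpute(x, k = 2)["s1", "F3"], 15)
})

test_that("test-set imputation draws only on training donors", {
  train <- matrix(c(1, 2, 3, 4), 2, 2,
                  dimnames = list(c("t1", "t2"), c("F1", "F2")))
  test <- matrix(c(1.1, NA, 100, NA), 2, 2, byrow = TRUE,
                 dimnames = list(c("u1", "u2"), c("F1", "F2")))
  filled <- knnImpute(test, k = 1, donors = train)
  expect_equal(filled["u1", "F2"], 3)  # nearest training sample t1
  expect_equal(filled["u2", "F2"], 4)  # nearest training sample t2
})

test_that("a feature missing in every donor is imputed as the scaled mean 0", {
  train <- matrix(c(1, 2, NA, NA), 2, 2,
                  dimnames = list(c("t1", "t2"), c("F1", "F2")))
  test <- matrix(c(1.5, NA), 1, 2, dimnames = list("u1", c("F1", "F2")))
  filled <- knnImpute(test, k = 5, donors = train)
  expect_equal(unname(filled["u1", "F2"]), 0)
  expect_identical(attr(filled, "imputedZero"), "F2")
})

test_that("integrateLayers assembles a valid standardized dataset", {
  co <- generateCohort(recoveryConfig(31))
  protStats <- runDifferential(co$protein)
  metStats <- runDifferential(co$metabolite)
  ds <- integrateLayers(protStats, metStats, co$protein, co$metabolite,
                        seed = 31)
  expect_s4_class(ds, "IntegratedDataset")
  expect_true(validObject(ds))
  expect_length(ds@trainIds, 9L)
  expect_length(ds@testIds, 4L)
  expect_false(anyNA(ds@trainValues))
  expect_false(anyNA(ds@testValues))
  nonConst <- !ds@scaling$constant
  expect_true(all(abs(colMeans(ds@trainValues)[nonConst]) < 0.5))
})
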