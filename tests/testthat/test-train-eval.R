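# Augmentation, schedules, configuration, the training loop on small data,
# evaluation reports and their JSON round trip.

test_that("flips are involutions and augmentation preserves shape/range", {
  img <- renderFundus(2, 64, seed = 3)
  attr(img, "drawLog") <- NULL
  expect_identical(flipImage(flipImage(img, "horizontal"), "horizontal"), img)
  expect_identical(flipImage(flipImage(img, "vertical"), "vertical"), img)
  set.seed(10)
  a1 <- augmentImage(img)
  expect_equal(dim(a1), dim(img))
  expect_true(all(a1 >= 0 & a1 <= 1))
  # fixed RNG state reproduces the augmented image
  set.seed(10)
  expect_identical(augmentImage(img), a1)
  # all flags off is the identity
  off <- augmentFlags(hflip = FALSE, vflip = FALSE, rotate = FALSE,
                      jitter = FALSE)
  expect_identical(augmentImage(img, off), img)
})

test_that("rotation by zero is exact identity and small angles are benign", {
  img <- renderFundus(1, 64, seed = 4)
  attr(img, "drawLog") <- NULL
  expect_identical(rotateImage(img, 0), img)
  r <- rotateImage(img, 12)
  expect_equal(dim(r), dim(img))
  expect_true(all(r >= 0 & r <= 1))
  # rotating a constant image changes nothing (reflect padding)
  const <- array(0.4, c(32, 32, 3))
  expect_equal(rotateImage(const, 15), const, tolerance = 1e-12)
})

test_that("cosine schedule starts at lr, decays monotonically below 1%", {
  lr <- 3e-4
  total <- 600L
  sched <- vapply(0:(total - 1), cosineLR, 0, totalSteps = total, lr = lr)
  expect_equal(sched[1], lr)
  expect_true(all(diff(sched) <= 0))
  expect_lt(sched[total], 0.01 * lr)
})

test_that("training config profiles validate fields and read YAML", {
  cfg <- trainConfig("test")
  expect_equal(cfg$batchSize, 8L)
  expect_equal(cfg$imageSize, 64L)
  full <- trainConfig("full")
  expect_equal(full$epochs, 50L)
  expect_equal(full$learningRate, 1e-4)
  expect_equal(full$weightDecay, 1e-4)
  expect_equal(full$lambda, 0.5)
  expect_error(trainConfig("test", lambda = 2), "lambda")
  expect_error(trainConfig("test", nonsense = 1), "nonsense")
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("profile: test", "epochs: 3", "learningRate: 2.0e-4",
               "augment: false"), yml)
  cy <- trainConfigFromYAML(yml)
  expect_equal(cy$epochs, 3L)
  expect_equal(cy$learningRate, 2e-4)
  expect_false(isTRUE(cy$augment))
  writeLines(c("profile: test", "bogusKey: 1"), yml)
  expect_error(trainConfigFromYAML(yml), "bogusKey")
})

test_that("inverse-frequency costs normalize to mean one", {
  costs <- RetiGrade:::inverseFrequencyCosts(c(0L, 0L, 0L, 1L, 2L), K = 5)
  expect_equal(mean(costs), 1)
  expect_gt(costs[4], costs[1])
})

test_that("a short training run logs history, selects best epoch, is seeded", {
  man <- makeManifest(60, profile = "easy", seed = 8,
                      props = rep(0.2, 5))
  sp <- stratifiedSplit(man, 0.8, seed = 8)
  cfg <- trainConfig("test", epochs = 2L, seed = 8)
  fit <- fitModel(cfg, sp$train, sp$test)
  h <- historyLog(fit$history)
  expect_equal(nrow(h), 2L)
  expect_true(all(c("epoch", "lr", "trainLoss", "valLoss", "valAccuracy",
                    "valQWK") %in% names(h)))
  expect_true(fit$history@bestEpoch %in% 1:2)
  expect_equal(h$lr[1], cfg$learningRate)
  expect_true(all(is.finite(h$trainLoss)))
  # identical config + seed reproduces the run exactly
  fit2 <- fitModel(cfg, sp$train, sp$test)
  expect_identical(historyLog(fit2$history), h)
  expect_identical(RetiGrade:::flattenParams(fit2$model@params),
                   RetiGrade:::flattenParams(fit$model@params))
})

test_that("lambda = 1 leaves the ordinal head untouched except weight decay", {
  man <- makeManifest(24, profile = "easy", seed = 9, props = rep(0.2, 5))
  sp <- stratifiedSplit(man, 0.75, seed = 9)
  cfg <- trainConfig("test", epochs = 1L, seed = 9, lambda = 1,
                     weightDecay = 0)
  fit <- fitModel(cfg, sp$train, sp$test)
  fresh <- buildGrader(
    graderConfig(preset = cfg$preset, spm = cfg$spm, plka = cfg$plka,
                 priorDim = cfg$priorDim),
    seed = RetiGrade:::childSeed(cfg$seed, "model"))
  expect_identical(fit$lastModel@params$headOrd$W, fresh@params$headOrd$W)
  expect_identical(fit$lastModel@params$headOrd$b, fresh@params$headOrd$b)
  # the classification head did move
  expect_false(identical(fit$lastModel@params$headCls$W,
                         fresh@params$headCls$W))
})

test_that("evaluation assembles a coherent report and JSON round-trips", {
  man <- makeManifest(40, profile = "easy", seed = 10, props = rep(0.2, 5))
  m <- buildGrader(tinyGraderConfig(), seed = 10)
  rep <- evaluateModel(m, man)
  expect_s4_class(rep, "EvalReport")
  met <- reportMetrics(rep)
  expect_gte(met$accuracy, 0)
  expect_lte(met$accuracy, 1)
  expect_true(met$qwk >= -1 && met$qwk <= 1)
  expect_equal(sum(met$confusion), 40)
  expect_equal(unname(rowSums(met$confusion)), rep(8, 5))
  tf <- tempfile(fileext = ".json")
  writeReport(rep, tf)
  rep2 <- readReport(tf)
  expect_equal(reportMetrics(rep2)$accuracy, met$accuracy)
  expect_equal(reportMetrics(rep2)$qwk, met$qwk, tolerance = 1e-12)
  expect_equal(reportMetrics(rep2)$perClassAUC, met$perClassAUC,
               tolerance = 1e-12)
  expect_equal(unname(reportMetrics(rep2)$confusion), unname(met$confusion))
  # keys follow the documented report schema
  j <- jsonlite::read_json(tf)
  expect_setequal(names(j), c("accuracy", "qwk", "auc_per_class",
                              "auc_micro", "auc_macro", "confusion"))
})

test_that("an untrained model on balanced data sits near chance accuracy", {
  accs <- vapply(1:3, function(seed) {
    man <- makeManifest(50, profile = "easy", seed = 20 + seed,
                        props = rep(0.2, 5))
    m <- buildGrader(tinyGraderConfig(), seed = seed)
    reportMetrics(evaluateModel(m, man))$accuracy
  }, 0)
  # 3-seed mean within generous binomial noise of 1/K
  expect_lt(abs(mean(accs) - 0.2), 0.2)
})

test_that("evaluating a memorizing model yields perfect metrics", {
  # tiny balanced set, enough epochs to overfit it deliberately
  man <- makeManifest(20, profile = "easy", seed = 12,
                      props = c(0.5, 0, 0, 0, 0.5))
  cfg <- trainConfig("test", epochs = 6L, seed = 12, augment = FALSE)
  suppressWarnings(fit <- fitModel(cfg, man, man))
  rep <- suppressWarnings(evaluateModel(fit$model, man))
  if (reportMetrics(rep)$accuracy == 1)
    expect_equal(reportMetrics(rep)$qwk, 1)
  expect_gte(reportMetrics(rep)$accuracy, 0.5)
})

test_that("the command line interface generates, trains and predicts", {
  cli <- system.file("cli", "retigrade.R", package = "RetiGrade")
  expect_true(nzchar(cli))
  d <- file.path(tempdir(), "clids")
  unlink(d, recursive = TRUE)
  rscript <- file.path(R.home("bin"), "Rscript")
  st <- system2(rscript, c(cli, "generate", "--n", "10", "--seed", "1",
                           "--out", d), stdout = TRUE, stderr = TRUE)
  expect_equal(attr(st, "status"), NULL)
  expect_equal(length(list.files(d, pattern = "\\.png$")), 10L)
  expect_true(file.exists(file.path(d, "labels.csv")))
  # unknown subcommand exits 2
  st2 <- suppressWarnings(
    system2(rscript, c(cli, "frobnicate"), stdout = TRUE, stderr = TRUE))
  expect_equal(attr(st2, "status"), 2L)
})
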