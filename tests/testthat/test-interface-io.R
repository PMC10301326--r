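test_that("curve CSV round-trips through write and read", {
  cv <- lux_simulate(true_rates(), lux_init(), seq(0, 15, length.out = 120))
  p <- file.path(tempdir(), "curve.csv")
  write_kinetic_curve(cv, p)
  back <- read_kinetic_curve(p, meta = cv$meta)
  expect_equal(back$t, cv$t, tolerance = 1e-12)
  expect_equal(back$y, cv$y, tolerance = 1e-12)
  expect_equal(back$signal, "bioluminescence")

  tr <- lux_curve(seq(0, 10, 0.5), exp(-seq(0, 10, 0.5)), "absorbance_380")
  p2 <- file.path(tempdir(), "trace.csv")
  write_kinetic_curve(tr, p2)
  expect_equal(read_kinetic_curve(p2, signal = "absorbance_380")$y, tr$y)
})

test_that("malformed CSVs are rejected with informative messages", {
  p <- file.path(tempdir(), "empty.csv")
  writeLines("time_s,intensity_au", p)
  expect_error(read_kinetic_curve(p), "no data rows")

  p2 <- file.path(tempdir(), "badheader.csv")
  writeLines(c("t,y", "0,1", "1,2"), p2)
  expect_error(read_kinetic_curve(p2), "header")

  p3 <- file.path(tempdir(), "shuffled.csv")
  writeLines(c("time_s,intensity_au", "0,1", "0.5,2", "0.25,3", "1,1"), p3)
  expect_error(read_kinetic_curve(p3), "line 4")

  p4 <- file.path(tempdir(), "nonnum.csv")
  writeLines(c("time_s,intensity_au", "0,1", "x,2"), p4)
  expect_error(read_kinetic_curve(p4), "line\\(s\\) 3")

  expect_error(read_kinetic_curve(file.path(tempdir(), "nope.csv")),
               "not found")
})

test_that("the pipeline runs end to end on synthetic data and is reproducible", {
  dir <- file.path(tempdir(), "pipe"); dir.create(dir, showWarnings = FALSE)
  synth <- generate_bioluminescence_dataset(
    seed = 2, t = seq(0, 15, length.out = 300))
  paths <- sprintf(file.path(dir, "curve_%d.csv"), 1:5)
  for (i in 1:5) write_kinetic_curve(synth$curves[[i]], paths[i])

  cfg <- list(
    curves = lapply(1:5, function(i)
      list(path = paths[i], decanal_uM = c(10, 20, 30, 40, 50)[i])),
    L0_uM = 1, F0_uM = 15, kd = 0.30, kdd = 0.05,
    seed = 3, n_starts = 4,
    out_dir = file.path(dir, "out"))
  rep1 <- run_pipeline(cfg)
  expect_true(all(file.exists(rep1$files)))

  tru <- unclass(true_rates())[1:5]
  est <- coef(rep1$fit)[1:5]
  expect_true(all(abs(est - tru) / tru < 0.15))
  expect_lt(rep1$fit$rel_error$pooled, 4.2)

  js <- jsonlite::read_json(file.path(dir, "out", "fit.json"))
  expect_equal(js$provenance$seed, 3)
  expect_length(js$provenance$inputs, 5)

  rep2 <- run_pipeline(cfg)
  expect_identical(coef(rep1$fit), coef(rep2$fit))

  cfg_bad <- cfg; cfg_bad$kd <- NULL
  expect_error(run_pipeline(cfg_bad), "kd and kdd")
})

test_that("a YAML config and dark-decay traces drive the same pipeline", {
  dir <- file.path(tempdir(), "pipe_yaml")
  dir.create(dir, showWarnings = FALSE)
  synth <- generate_bioluminescence_dataset(
    seed = 4, t = seq(0, 15, length.out = 250))
  paths <- sprintf(file.path(dir, "c%d.csv"), 1:5)
  for (i in 1:5) write_kinetic_curve(synth$curves[[i]], paths[i])

  tr445 <- generate_absorbance_trace("bi", k = c(2, 0.30),
                                     amplitude = c(-0.1, -0.15),
                                     offset = 0.45, t = seq(0, 40, 0.02))
  tr380 <- generate_absorbance_trace("mono", k = 0.05, amplitude = 0.2,
                                     offset = 0.05, t = seq(0, 120, 0.2),
                                     signal = "absorbance_380")
  p445 <- file.path(dir, "kd.csv"); p380 <- file.path(dir, "kdd.csv")
  write_kinetic_curve(tr445$trace, p445)
  write_kinetic_curve(tr380$trace, p380)

  cfg <- list(
    curves = lapply(1:5, function(i)
      list(path = paths[i], decanal_uM = c(10, 20, 30, 40, 50)[i])),
    kd = list(trace = p445, windows = list(c(0, 1.2), c(8, 40))),
    kdd = list(trace = p380, windows = list(c(0, 120))),
    seed = 1, n_starts = 3,
    out_dir = file.path(dir, "out"))
  yml <- file.path(dir, "run.yaml")
  yaml::write_yaml(cfg, yml)
  rep <- run_pipeline(yml)
  expect_equal(rep$dark_decay$kd$kd, 0.30, tolerance = 0.02)
  expect_equal(rep$dark_decay$kdd$k, 0.05, tolerance = 0.02)
  expect_lt(rep$fit$rel_error$pooled, 4.2)
})
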