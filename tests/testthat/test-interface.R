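test_that("derived seeds are deterministic, index-sensitive and collision-free at scale", {
  expect_identical(derive_seed(42L, "trial", 7), derive_seed(42L, "trial", 7))
  expect_false(derive_seed(42L, "trial", 7) == derive_seed(42L, "trial", 8))
  expect_false(derive_seed(42L, "trial", 7) == derive_seed(43L, "trial", 7))
  expect_false(derive_seed(42L, "trial", 7) == derive_seed(42L, "cued", 7))

  labels <- c("trial-noise", "cued-trial", "cued-sequence", "learn-session",
              "sweep-level", "sweep-probe", "race-trial", "boot-a")
  seeds <- unlist(lapply(labels, function(L)
    vapply(0:12499, function(i) derive_seed(7L, L, i), integer(1))))
  expect_length(seeds, 100000L)
  expect_false(any(duplicated(seeds)))
  expect_true(all(seeds >= 0 & seeds < 2^31))
})

test_that("an empty config file yields the documented defaults", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", f)
  cfg <- load_config(f)
  expect_equal(unclass(cfg)[names(default_config())],
               default_config()[names(default_config())],
               ignore_attr = TRUE)
})

test_that("config validation names the violated constraint and the offending key", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("network:\n  dt: 50\n  tau: 100\n", f)
  expect_error(load_config(f), "dt <= tau/10", fixed = TRUE)

  writeLines("networkx:\n  dt: 1\n", f)
  expect_error(load_config(f), "unknown configuration key.*networkx")

  writeLines("network:\n  dtt: 1\n", f)
  expect_error(load_config(f), "unknown key.*network.*dtt")

  writeLines("cued:\n  direct_bias: 0.4\n", f)
  expect_error(load_config(f), "direct_bias")
})

test_that("load -> save -> load is the identity on randomized valid configs", {
  set.seed(99)
  for (k in 1:25) {
    cfg_list <- list(
      network = list(tau = runif(1, 50, 200), noise_sd = runif(1, 0, 0.1),
                     w_self = runif(1, 0, 2), dt = 1),
      decision = list(threshold = runif(1, 0.5, 2),
                      deadline = runif(1, 800, 2000)),
      learning = list(alpha_q = runif(1, 0.01, 0.5),
                      delta = runif(1, 0.005, 0.05)),
      seed = sample.int(1e6, 1)
    )
    f1 <- tempfile(fileext = ".yaml")
    f2 <- tempfile(fileext = ".yaml")
    yaml::write_yaml(cfg_list, f1)
    c1 <- load_config(f1)
    save_config(c1, f2)
    c2 <- load_config(f2)
    expect_equal(unclass(c1), unclass(c2), ignore_attr = TRUE)
    unlink(c(f1, f2))
  }
})

test_that("trial sets survive the CSV round trip field-wise", {
  pre <- channel_preset("gonogo")
  ts <- run_trials(pre$params, ratio_input(1.6), quick_dp(), n = 30, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trials(ts, f)
  back <- read_trials(f)
  expect_identical(as.data.frame(back), as.data.frame(ts))
  expect_identical(attr(back, "params_fingerprint"),
                   attr(ts, "params_fingerprint"))
  expect_identical(attr(back, "base_seed"), attr(ts, "base_seed"))

  # absent RT is an empty field, not 0, and reads back as NA
  raw <- readLines(f)
  nogo_rows <- which(ts$label == "no-go")
  if (length(nogo_rows)) {
    line <- strsplit(raw[nogo_rows[1] + 1L], ",")[[1L]]
    expect_identical(line[4], "")
  }
})

test_that("an empty trial set writes a header-only CSV with a valid sidecar", {
  empty <- bgcompete:::new_bg_trials(
    data.frame(trial = integer(0), condition = character(0),
               label = character(0), rt_ms = numeric(0),
               crossed = logical(0), seed = integer(0)),
    params_fingerprint = "none", base_seed = 1L, kind = "gonogo")
  f <- withr::local_tempfile(fileext = ".csv")
  write_trials(empty, f)
  expect_length(readLines(f), 1L)
  back <- read_trials(f)
  expect_equal(nrow(back), 0L)
  expect_identical(names(back), names(empty))
})

test_that("trajectory export writes the documented TSV contract", {
  pre <- channel_preset("gonogo")
  tr <- simulate_channel(pre$params, pre$input, horizon = 50, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, f)
  df <- read.delim(f)
  expect_identical(names(df), c("time_ms", "d_rate", "i_rate"))
  expect_equal(nrow(df), 51L)
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(meta$seed, 2L)
})

test_that("repeated runs produce byte-identical output files", {
  pre <- channel_preset("gonogo")
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  for (d in c(dir1, dir2)) {
    ts <- run_trials(pre$params, ratio_input(1.6), quick_dp(), n = 25, seed = 77)
    write_trials(ts, file.path(d, "trials.csv"))
  }
  expect_identical(unname(tools::md5sum(file.path(dir1, "trials.csv"))),
                   unname(tools::md5sum(file.path(dir2, "trials.csv"))))
})

test_that("the command-line interface is reproducible end to end", {
  cli <- system.file("cli", "bgcompete.R", package = "bgcompete")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  for (d in c(dir1, dir2)) {
    status <- system2(rscript,
                      c(cli, "simulate", "--n-trials", "15", "--seed", "5",
                        "--out-dir", d, "--log-level", "warning"),
                      stdout = FALSE, stderr = FALSE)
    expect_equal(status, 0L)
  }
  f1 <- file.path(dir1, "trials.csv")
  f2 <- file.path(dir2, "trials.csv")
  expect_true(file.exists(f1))
  expect_identical(readLines(f1), readLines(f2))
  s1 <- jsonlite::read_json(file.path(dir1, "summary.json"))
  expect_true(is.numeric(s1$go_rate))
})
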