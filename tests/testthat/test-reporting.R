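test_that("configuration is validated before any simulation", {
  expect_error(benchmark_config(models = "ventricular"), "unknown model")
  expect_error(benchmark_config(models = "grandi"), "plugin slot")
  expect_error(benchmark_config(dt = -1))
})

test_that("an empty model list yields an empty report without error", {
  cfg <- benchmark_config(models = character(0), protocols = "table1")
  rep <- run_benchmark(cfg)
  expect_s3_class(rep, "benchmark_report")
  expect_true(is.null(rep$tables$table1) || nrow(rep$tables$table1) == 0)
})

test_that("reference tables ship the published values", {
  t1 <- reference_tables("table1")
  expect_equal(t1$C[t1$property == "apd90_ms"], 294.83)
  expect_equal(t1$N[t1$property == "rmp_mv"], -74.15)
  r <- reference_tables("restitution_bcl04")
  expect_equal(r$C[r$metric == "cv_mm_per_s" & r$variant == "control"],
               751.9)
  expect_true(is.na(r$G[r$metric == "erp_ms" & r$variant == "control"]))
})

test_that("comparison against reference applies the tolerance policy per property", {
  comp <- data.frame(property = c("apd90_ms", "rmp_mv", "cv_mm_per_s"),
                     value = c(294, -81.0, 751))
  ref <- data.frame(property = c("apd90_ms", "rmp_mv", "cv_mm_per_s"),
                    value = c(294.83, -81.04, 751.9))
  out <- compare_to_reference(comp, ref)
  expect_true(all(out$status == "pass"))
  # one cell off by 10% with a 5% tolerance: flagged as a single fail
  comp$value[1] <- 294.83 * 1.10
  out2 <- compare_to_reference(comp, ref)
  expect_identical(out2$status[1], "fail")
  expect_true(all(out2$status[-1] == "pass"))
  # undefined reference cells are skipped, not failed
  ref$value[3] <- NA
  out3 <- compare_to_reference(comp, ref)
  expect_identical(out3$status[3], "skipped")
  # mismatched shapes
  expect_error(compare_to_reference(comp[1:2, ], ref), "mismatched")
})

test_that("report bundles are written as CSVs with a manifest", {
  dir <- tempfile("report")
  rep <- structure(list(config = benchmark_config(models = "courtemanche",
                                                  protocols = "table1"),
                        tables = list(table1 = data.frame(model = "c",
                                                          apd90_ms = 1))),
                   class = "benchmark_report")
  files <- write_report(rep, dir)
  expect_true(file.exists(file.path(dir, "table1.csv")))
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_true("models" %in% man$key)
})
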