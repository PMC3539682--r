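test_that("rate-independent mock APD gives a flat restitution curve", {
  p1 <- mock_proto(0.6)
  p2 <- mock_proto(0.9)
  expect_true(all(p1$capture) && all(p2$capture))
  expect_lt(abs(p1$apd90 - p2$apd90), 2)
  expect_lt(abs(p1$apd90 - 150) / 150, 0.05)
})

test_that("mock strand ERP equals the built-in refractory period within 2 ms", {
  erp <- measure_erp(mock_proto(0.6))
  expect_lt(abs(as.numeric(erp) - 200), 2)
})

test_that("wavelength is the exact product of ERP and CV", {
  expect_equal(wavelength(302, 751.9), 302 * 751.9 / 1000)
  expect_equal(wavelength(0, 600), 0)
  expect_true(is.na(wavelength(NA, 600)))
  p <- mock_proto(0.6)
  erp <- as.numeric(measure_erp(p))
  expect_identical(wavelength(erp, p$cv), erp * p$cv / 1000)
})

test_that("the strand protocol records capture failure instead of raising", {
  # a BCL shorter than the mock refractory period cannot capture 1:1
  a <- mock_strand_args()
  p <- run_strand_protocol(std_mock(), bcl = 0.18, sigma = a$sigma,
                           nv = a$nv, dx = a$dx)
  expect_false(all(p$capture))
  expect_true(is.finite(p$failed_beat))
  expect_true(is.na(p$apd90))
  expect_error(measure_erp(p), "failed at beat")
})

test_that("strand results are bit-identical across reruns (determinism)", {
  a <- mock_strand_args()
  p1 <- run_strand_protocol(std_mock(), bcl = 0.6, sigma = a$sigma,
                            nv = a$nv, dx = a$dx)
  p2 <- run_strand_protocol(std_mock(), bcl = 0.6, sigma = a$sigma,
                            nv = a$nv, dx = a$dx)
  expect_identical(p1$apd90, p2$apd90)
  expect_identical(p1$cv, p2$cv)
  expect_identical(p1$state_s1, p2$state_s1)
})
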