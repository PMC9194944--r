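# Frozen single-level coefficients were computed independently with a
# reference filter-bank implementation (8-tap Daubechies analysis pair,
# whole-sample symmetric extension) on x[n] = sin(0.3 n), n = 0..31.
test_that("db4 symmetric decomposition matches reference coefficients", {
  x <- sin(0.3 * (0:31))
  dec <- decompose_column(x, wavelet_spec("db4", levels = 1))
  cA <- dec$levels[[1]]$approx
  cD <- dec$levels[[1]]$detail
  expect_length(cA, 19L)
  expect_equal(cA[1:5],
               c(1.316046402955145, 0.789912057741904, -0.001559987713935,
                 0.424868879192306, 1.112292826624526),
               tolerance = 1e-12)
  expect_equal(cD[1:5],
               c(0.01219650741198, 0.018979456734785, -0.021381656793351,
                 -0.003888856390341, -0.003870650491609),
               tolerance = 1e-12)
  # cascaded level-3 approximation from the same reference
  dec3 <- decompose_column(x, wavelet_spec("db4", levels = 3))
  a3 <- dec3$levels[[3]]$approx
  expect_length(a3, 10L)
  expect_equal(a3[1:3],
               c(1.422948672494848, 1.565812618197712, 1.496669658407494),
               tolerance = 1e-12)
})

test_that("haar periodization matches the closed-form averages/differences", {
  dec <- decompose_column(1:8, wavelet_spec("haar", 1, "periodic"))
  expect_equal(dec$levels[[1]]$approx, c(3, 7, 11, 15) / sqrt(2))
  expect_equal(dec$levels[[1]]$detail, rep(-1 / sqrt(2), 4))
})

test_that("decomposition is linear: the zero signal maps to zero bands", {
  dec <- decompose_column(numeric(64), wavelet_spec("db4", 4))
  for (lv in dec$levels) {
    expect_true(all(lv$approx == 0))
    expect_true(all(lv$detail == 0))
  }
})

test_that("orthogonal wavelets preserve energy under periodic extension", {
  set.seed(11)
  for (fam in c("haar", "db2", "db4")) {
    x <- rnorm(64)
    dec <- decompose_column(x, wavelet_spec(fam, 4, "periodic"))
    energy <- sum(dec$levels[[4]]$approx^2) +
      sum(vapply(dec$levels, function(l) sum(l$detail^2), 0))
    expect_equal(energy, sum(x^2), tolerance = 1e-10)
  }
})

test_that("multi-level decomposition reconstructs the input exactly", {
  set.seed(12)
  filters <- stackrp:::wavelet_filters("db4")
  x <- numeric(64)
  x[29] <- 1  # impulse
  for (signal in list(x, rnorm(64))) {
    dec <- decompose_column(signal, wavelet_spec("db4", 4))
    lens <- c(length(signal),
              vapply(dec$levels, function(l) length(l$approx), 0L))
    rec <- dec$levels[[4]]$approx
    for (j in 4:1)
      rec <- stackrp:::idwt_step(rec, dec$levels[[j]]$detail, filters,
                                 lens[j])
    expect_equal(rec, signal, tolerance = 1e-10)
  }
})

test_that("band statistics are (max, min, mean, population sd)", {
  expect_equal(unname(band_statistics(c(1, 2, 3, 4))),
               c(4, 1, 2.5, sqrt(1.25)))
  expect_equal(unname(band_statistics(rep(3.7, 5))), c(3.7, 3.7, 3.7, 0))
  expect_equal(unname(band_statistics(2.5)), c(2.5, 2.5, 2.5, 0))
  expect_error(band_statistics(numeric(0)), "non-empty")
})

test_that("leading DCT coefficients match the direct cosine-sum formula", {
  expect_equal(dct_leading_coefficients(numeric(6), 5), numeric(5))
  # constant signal is DC-only
  cc <- dct_leading_coefficients(rep(2, 8), 5)
  expect_equal(cc[-1], numeric(4), tolerance = 1e-12)
  x <- as.numeric(1:8)
  expect_equal(dct_leading_coefficients(x, 5), brute_dct2(x, 5),
               tolerance = 1e-12)
  # and against an independently computed transform of the same signal
  expect_equal(dct_leading_coefficients(x, 5),
               c(72, -25.76929209082055, 0, -2.693819203615763, 0),
               tolerance = 1e-12)
  # short bands are zero-padded
  expect_equal(dct_leading_coefficients(c(1, 2), 5)[3:5], numeric(3))
})

test_that("feature block has the documented shape, order and determinism", {
  set.seed(13)
  profile <- encode_sequence(random_sequence(200))
  feats <- extract_dwt_features(profile)
  expect_length(feats, 1040L)
  # per attribute column: 4 levels x (4 + 4 + 5) = 52
  a_feats <- feats[startsWith(names(feats), "dwt.A.")]
  expect_length(a_feats, 52L)
  expect_equal(names(feats)[1:13],
               paste0("dwt.A.l1.", c("a.max", "a.min", "a.mean", "a.sd",
                                     "d.max", "d.min", "d.mean", "d.sd",
                                     paste0("dct", 1:5))))
  expect_false(anyDuplicated(names(feats)) > 0)
  expect_identical(feats, extract_dwt_features(profile))
  # all-zero profile maps to all-zero features
  zero <- matrix(0, 64, 20)
  expect_true(all(extract_dwt_features(zero) == 0))
})

test_that("truncation mode emits the approximation band head instead of DCT", {
  profile <- encode_sequence("ACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWY")
  tr <- extract_dwt_features(profile, dct_mode = "truncate")
  dec <- decompose_column(profile[, 1], wavelet_spec())
  expect_equal(unname(tr[paste0("dwt.A.l1.dct", 1:5)]),
               dec$levels[[1]]$approx[1:5])
})

test_that("too-short signals are rejected with the minimum length named", {
  expect_error(decompose_column(c(1, 2, 3), wavelet_spec("db4")), "minimum")
  expect_error(extract_dwt_features(matrix(1, 3, 20)), "minimum")
})
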