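test_that("the packaged hypertension table reads to a validated object", {
  agg <- hypertension_trials()
  expect_s3_class(agg, "meta_aggregate")
  expect_equal(length(unique(agg$study)), 10L)
  expect_equal(nrow(agg), 20L)
  atm <- agg[agg$study == "ATMH" & agg$arm == "treated", ]
  expect_equal(atm$n, 780)
  expect_equal(atm$mean_base, 152.28)
  expect_equal(atm$corr, 0.265)
  expect_equal(sum(agg$n), 28580)
})

test_that("reading rejects degenerate and malformed tables", {
  expect_error(read_aggregate(textConnection("")), "empty")
  expect_error(read_aggregate(textConnection("study,arm,n\n")), "empty")
  # missing required column is named
  expect_error(
    read_aggregate(textConnection(
      "study,arm,n,mean_base,sd_base,mean_final\nA,treated,10,1,1,1")),
    "sd_final")
  # n < 3 cites study and arm
  long <- paste("study,arm,n,mean_base,sd_base,mean_final,sd_final,corr",
                "A,treated,2,150,15,130,16,0.3",
                "A,control,50,150,15,140,17,0.3", sep = "\n")
  expect_error(read_aggregate(textConnection(long)), "A/treated")
  # negative SD
  long2 <- sub("15,130", "-1,130", long)
  long2 <- sub("n,2,", "n,20,", long2)
  expect_error(read_aggregate(textConnection(sub(",2,", ",20,", long2))),
               "sd_base")
})

test_that("long and wide layouts and a write/read round trip agree", {
  agg <- small_agg()
  f <- tempfile(fileext = ".csv")
  write_aggregate(agg, f)
  back <- read_aggregate(f, layout = "long", outcome_label = "SBP",
                         outcome_units = "mmHg")
  expect_equal(as.data.frame(back), as.data.frame(agg))
  # wide layout with custom column names through column_map
  wide <- paste(
    paste("trial", "n_t", "n_c", "mean_base_t", "sd_base_t", "mean_base_c",
          "sd_base_c", "mean_final_t", "sd_final_t", "mean_final_c",
          "sd_final_c", "corr_t", "corr_c", sep = "\t"),
    paste("A", "80", "75", "152.3", "15.2", "153.1", "15.7", "132.9", "16.7",
          "139.8", "17.9", "0.27", "0.28", sep = "\t"),
    sep = "\n")
  w <- read_aggregate(textConnection(wide), layout = "wide",
                      column_map = c(study = "trial"))
  expect_equal(w$n, c(80, 75))
  expect_equal(w$mean_final[w$arm == "control"], 139.8)
})

test_that("correlation recovery from the change-score SD is exact algebra", {
  # Pythagorean case: change SD 5 from SDs 3, 4 implies zero correlation
  expect_equal(corr_from_change_sd(3, 4, 5), 0)
  expect_equal(sd_change_from_corr(3, 4, 0), 5)
  # perfectly correlated limit is rejected as boundary-inconsistent
  expect_error(corr_from_change_sd(2, 2, 0), "incompatible")
  # change SD shrinks to zero monotonically as the correlation approaches 1
  eps <- 10^-(1:6)
  sds <- sd_change_from_corr(7, 7, 1 - eps)
  expect_true(all(diff(sds) < 0) && sds[6] < 0.02)
  # round trip over every arm of the hypertension table to 1e-12
  agg <- hypertension_trials()
  sdc <- sd_change_from_corr(agg$sd_base, agg$sd_final, agg$corr)
  expect_equal(corr_from_change_sd(agg$sd_base, agg$sd_final, sdc),
               agg$corr, tolerance = 1e-12)
})

test_that("shared correlation recovery from the SE of the change difference", {
  tr <- list(n = 780, sd_base = 15.25, sd_final = 16.72)
  ct <- list(n = 750, sd_base = 15.73, sd_final = 17.85)
  fwd <- function(r) {
    v <- (tr$sd_base^2 + tr$sd_final^2 - 2 * r * tr$sd_base * tr$sd_final) / tr$n +
      (ct$sd_base^2 + ct$sd_final^2 - 2 * r * ct$sd_base * ct$sd_final) / ct$n
    sqrt(v)
  }
  expect_equal(corr_from_se_diff(tr, ct, fwd(0.5)), 0.5, tolerance = 1e-12)
  # zero-correlation case: se^2 equal to the sum of the four variance terms
  se0 <- sqrt(tr$sd_base^2 / tr$n + tr$sd_final^2 / tr$n +
                ct$sd_base^2 / ct$n + ct$sd_final^2 / ct$n)
  expect_equal(corr_from_se_diff(tr, ct, se0), 0, tolerance = 1e-12)
  expect_error(corr_from_se_diff(tr, ct, 1e-9), "incompatible")

  # simulation oracle: recover the correlation of a large bivariate-normal
  # two-arm sample from its summary statistics alone
  set.seed(401)
  n <- 4000; rho <- 0.4
  mk <- function() {
    b <- rnorm(n, 160, 15)
    f <- 140 + rho * 16 / 15 * (b - 160) + rnorm(n, 0, 16 * sqrt(1 - rho^2))
    cbind(b, f)
  }
  A <- mk(); B <- mk()
  arm <- function(m) list(n = n, sd_base = sd(m[, 1]), sd_final = sd(m[, 2]))
  sed <- sqrt(var(A[, 2] - A[, 1]) / n + var(B[, 2] - B[, 1]) / n)
  r <- corr_from_se_diff(arm(A), arm(B), sed)
  expect_lt(abs(r - rho), 3 / sqrt(n))
})

test_that("recover_correlations fills gaps and errors on dead ends", {
  agg <- small_agg()
  sdc <- sd_change_from_corr(agg$sd_base, agg$sd_final, agg$corr)
  gap <- agg
  gap$sd_change <- sdc
  gap$corr[1:4] <- NA
  got <- recover_correlations(gap)
  expect_equal(got$corr, agg$corr, tolerance = 1e-12)
  # via the study-level SE of the change difference: one shared value per study
  gap2 <- agg
  gap2$corr[gap2$study == "B"] <- NA
  i <- which(gap2$study == "B")
  gap2$se_diff_change[i] <- sqrt(sum(sdc[i]^2 / gap2$n[i]))
  got2 <- recover_correlations(gap2)
  expect_equal(got2$corr[i][1], got2$corr[i][2])
  expect_true(all(abs(got2$corr[i] - agg$corr[i]) < 0.05))
  # no route at all
  gap3 <- agg
  gap3$corr[5] <- NA
  expect_error(recover_correlations(gap3), "not recoverable")
})

test_that("baseline shifts move treated means only and cancel in change scores", {
  agg <- hypertension_trials()
  sh <- hypertension_shifts()
  shifted <- apply_baseline_shift(agg, sh)
  atm <- shifted[shifted$study == "ATMH" & shifted$arm == "treated", ]
  expect_equal(atm$mean_base, 147.28)
  expect_equal(atm$mean_final, 127.85)
  expect_equal(shifted[shifted$arm == "control", ],
               agg[agg$arm == "control", ], ignore_attr = TRUE)
  expect_equal(shifted$sd_base, agg$sd_base)
  expect_equal(shifted$sd_final, agg$sd_final)
  expect_equal(shifted$corr, agg$corr)
  expect_equal(shifted$n, agg$n)
  # per-arm mean change is preserved exactly
  expect_equal(shifted$mean_final - shifted$mean_base,
               agg$mean_final - agg$mean_base)
  # all-zero shifts are the identity; unknown study errors
  expect_equal(apply_baseline_shift(agg, c(ATMH = 0)), agg)
  expect_error(apply_baseline_shift(agg, c(NOPE = -5)), "unknown study")
})
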