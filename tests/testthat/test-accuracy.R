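# four visits with wut_counts 0..3 and reference euh/euh/deh/deh
four_visit_fixture <- function() {
  key <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:4), condition = "FL",
    day = 1L, timepoint = "morning"
  )
  list(
    wut = dplyr::bind_cols(key, tibble::tibble(wut_count = 0:3)),
    ref = dplyr::bind_cols(key, tibble::tibble(
      marker = "USG", dehydrated = c(FALSE, FALSE, TRUE, TRUE)
    ))
  )
}

test_that("contingency counts match a by-hand enumeration", {
  fix <- four_visit_fixture()
  tab <- build_contingency(fix$wut, fix$ref, "USG", k = 2)
  expect_equal(tab$TP, 2); expect_equal(tab$TN, 2)
  expect_equal(tab$FP, 0); expect_equal(tab$FN, 0)
  expect_equal(tab$n_scorable, 4)

  # k = 1 when every visit scores >= 1: nothing can be test-negative
  wut_all <- fix$wut; wut_all$wut_count <- c(1L, 2L, 3L, 3L)
  tab1 <- build_contingency(wut_all, fix$ref, "USG", k = 1)
  expect_equal(tab1$FN, 0); expect_equal(tab1$TN, 0)

  # totals always partition the scorable visits
  for (k in 1:3) {
    t_k <- build_contingency(fix$wut, fix$ref, "USG", k)
    expect_equal(t_k$TP + t_k$FP + t_k$FN + t_k$TN, t_k$n_scorable)
  }
})

test_that("missing reference calls are excluded listwise per marker", {
  fix <- small_cohort(seed = 44)
  wut <- score_wut(fix$visits)
  ref <- classify_reference(fix$visits)
  for (mk in c("USG", "UOSM")) {
    expect_equal(build_contingency(wut, ref, mk, 2)$n_scorable, 288)
  }
  expect_equal(build_contingency(wut, ref, "POSM", 2)$n_scorable, 271)
})

test_that("an empty stratum yields a zero table with a warning", {
  fix <- four_visit_fixture()  # morning FL only
  expect_warning(
    tab <- build_contingency(fix$wut, fix$ref, "USG", 2,
                             timepoint = "afternoon", condition = "EUH"),
    "empty stratum"
  )
  expect_equal(tab$TP + tab$FP + tab$FN + tab$TN, 0)
  m <- compute_metrics(tab)
  expect_true(is.na(m$sensitivity) && is.na(m$specificity))
})

test_that("metrics match hand arithmetic and handle zero denominators explicitly", {
  m <- compute_metrics(tibble::tibble(TP = 9, FP = 1, FN = 2, TN = 8))
  expect_equal(m$sensitivity, 9 / 11)
  expect_equal(m$specificity, 8 / 9)
  expect_equal(m$ppv, 0.9)
  expect_equal(m$npv, 0.8)
  expect_equal(m$youden_j, 9 / 11 + 8 / 9 - 1)
  expect_true(all(is.na(c(m$sensitivity_reason, m$specificity_reason,
                          m$ppv_reason, m$npv_reason))))
  expect_match(attr(m, "interpretation"), "specificity")

  none_pos <- compute_metrics(tibble::tibble(TP = 0, FP = 3, FN = 0, TN = 7))
  expect_true(is.na(none_pos$sensitivity))
  expect_equal(none_pos$sensitivity_reason, "no reference-positive visits")
  expect_true(is.na(none_pos$youden_j))

  perfect <- compute_metrics(tibble::tibble(TP = 5, FP = 0, FN = 0, TN = 6))
  expect_equal(c(perfect$sensitivity, perfect$specificity,
                 perfect$ppv, perfect$npv), rep(1, 4))

  expect_error(compute_metrics(tibble::tibble(TP = -1, FP = 0, FN = 0, TN = 0)),
               "non-negative")
})

test_that("metrics equal the brute-force oracle on randomised fixtures", {
  set.seed(90210)
  for (rep in 1:25) {
    fix <- random_scored_fixture(n = sample(20:60, 1))
    mk <- sample(c("USG", "UOSM", "POSM"), 1)
    k <- sample(1:3, 1)
    tp <- sample(c("morning", "afternoon", "both"), 1)
    cond <- sample(c("EUH", "FL", "both"), 1)
    got <- suppressWarnings(
      compute_metrics(build_contingency(fix$wut, fix$ref, mk, k, tp, cond)))
    want <- oracle_accuracy(fix$wut, fix$ref, mk, k, tp, cond)
    expect_equal(got$TP, want$TP)
    expect_equal(got$FP, want$FP)
    expect_equal(got$FN, want$FN)
    expect_equal(got$TN, want$TN)
    expect_equal(got$sensitivity, want$sensitivity)
    expect_equal(got$specificity, want$specificity)
    expect_equal(got$ppv, want$ppv)
    expect_equal(got$npv, want$npv)
  }
})

test_that("operating points agree with pROC on a random cohort", {
  skip_if_not_installed("pROC")
  fix <- small_cohort(seed = 77)
  wut <- score_wut(fix$visits)
  ref <- classify_reference(fix$visits)
  joined <- dplyr::inner_join(wut, ref[ref$marker == "USG", ],
                              by = c("subject_id", "condition", "day", "timepoint"))
  roc <- suppressMessages(pROC::roc(joined$dehydrated, joined$wut_count,
                                    direction = "<", quiet = TRUE))
  pts <- roc_points(wut, ref, "USG")
  for (k in 1:3) {
    co <- pROC::coords(roc, x = k - 0.5, input = "threshold",
                       ret = c("sensitivity", "specificity"))
    expect_equal(pts$tpr[pts$k == k & !is.na(pts$k)], co$sensitivity)
    expect_equal(1 - pts$fpr[pts$k == k & !is.na(pts$k)], co$specificity)
  }
})

test_that("roc_points carries anchors and degenerate data collapse correctly", {
  fix <- four_visit_fixture()
  # perfectly separating: dehydrated score 3, euhydrated score 0
  sep <- fix$wut; sep$wut_count <- c(0L, 0L, 3L, 3L)
  pts <- roc_points(sep, fix$ref, "USG")
  expect_equal(pts$point[c(1, nrow(pts))], c("anchor_00", "anchor_11"))
  expect_equal(pts$fpr[c(1, nrow(pts))], c(0, 1))
  expect_equal(pts$tpr[c(1, nrow(pts))], c(0, 1))
  op <- pts[!is.na(pts$k), ]
  expect_equal(op$fpr, rep(0, 3))
  expect_equal(op$tpr, rep(1, 3))

  # constant score: every point at (0,0) or (1,1)
  const0 <- fix$wut; const0$wut_count <- rep(0L, 4)
  op0 <- roc_points(const0, fix$ref, "USG")
  op0 <- op0[!is.na(op0$k), ]
  expect_true(all(op0$fpr == 0 & op0$tpr == 0))
  const3 <- fix$wut; const3$wut_count <- rep(3L, 4)
  op3 <- roc_points(const3, fix$ref, "USG")
  op3 <- op3[!is.na(op3$k), ]
  expect_true(all(op3$fpr == 1 & op3$tpr == 1))

  # one reference class only: coordinates undefined with a reason
  ref_all_pos <- fix$ref; ref_all_pos$dehydrated <- TRUE
  und <- roc_points(fix$wut, ref_all_pos, "USG")
  und <- und[!is.na(und$k), ]
  expect_true(all(is.na(und$fpr)))
  expect_match(und$reason, "no reference-negative", all = TRUE)
})

test_that("sensitivity falls and specificity rises as k increases", {
  set.seed(5150)
  for (rep in 1:15) {
    fix <- random_scored_fixture(n = sample(25:80, 1))
    for (mk in c("USG", "UOSM", "POSM")) {
      ms <- lapply(1:3, function(k) suppressWarnings(
        compute_metrics(build_contingency(fix$wut, fix$ref, mk, k))))
      sens <- vapply(ms, function(m) m$sensitivity, numeric(1))
      spec <- vapply(ms, function(m) m$specificity, numeric(1))
      if (!anyNA(sens)) expect_true(all(diff(sens) <= 1e-12))
      if (!anyNA(spec)) expect_true(all(diff(spec) >= -1e-12))
    }
  }
})

test_that("cut-off determination follows the configured criterion", {
  pts <- tibble::tibble(point = paste0("WUT", 1:3), k = 1:3,
                        fpr = c(0.5, 0.1, 0.0), tpr = c(0.9, 0.8, 0.4))
  # Youden J: 0.4, 0.7, 0.4 -> k = 2
  y <- cutoff_value(pts, "youden")
  expect_equal(y$value, 0.7)
  expect_equal(y$k, 2L)
  expect_equal(y$criterion, "youden")

  # distances to (0,1): 0.5099, 0.2236, 0.6 -> also k = 2 here
  d <- cutoff_value(pts, "closest_to_01")
  expect_equal(d$value, sqrt(0.1^2 + 0.2^2))
  expect_equal(d$k, 2L)

  # criteria can disagree: J favours the sensitive point, distance the specific
  pts2 <- tibble::tibble(point = paste0("WUT", 1:3), k = 1:3,
                         fpr = c(0.45, 0.05, 0.00), tpr = c(1.0, 0.58, 0.50))
  expect_equal(cutoff_value(pts2, "youden")$k, 1L)          # J = .55, .53, .50
  expect_equal(cutoff_value(pts2, "closest_to_01")$k, 2L)   # d = .450, .423, .500

  # single perfect point
  p1 <- tibble::tibble(point = "WUT2", k = 2L, fpr = 0, tpr = 1)
  expect_equal(cutoff_value(p1)$value, 1.0)
  expect_equal(cutoff_value(p1, "closest_to_01")$value, 0.0)

  # ties break toward larger k (the more specific call)
  tie <- tibble::tibble(point = paste0("WUT", 1:3), k = 1:3,
                        fpr = c(0.2, 0.1, 0.0), tpr = c(0.9, 0.8, 0.7))
  expect_equal(cutoff_value(tie, "youden")$k, 3L)  # J = 0.7 at every k

  # all undefined
  und <- tibble::tibble(point = paste0("WUT", 1:3), k = 1:3,
                        fpr = NA_real_, tpr = NA_real_)
  res <- cutoff_value(und)
  expect_true(is.na(res$value))
  expect_match(res$reason, "undefined")
})

test_that("pooled stratum counts equal the sum of the per-stratum tables", {
  fix <- small_cohort(seed = 55)
  wut <- score_wut(fix$visits)
  ref <- classify_reference(fix$visits)
  for (mk in c("USG", "POSM")) {
    for (k in 1:3) {
      pooled <- build_contingency(wut, ref, mk, k)
      parts <- lapply(c("morning", "afternoon"), function(tp) {
        lapply(c("EUH", "FL"), function(cond) {
          build_contingency(wut, ref, mk, k, tp, cond)
        })
      })
      parts <- dplyr::bind_rows(unlist(parts, recursive = FALSE))
      for (cell in c("TP", "FP", "FN", "TN")) {
        expect_equal(sum(parts[[cell]]), pooled[[cell]])
      }
    }
  }
})

test_that("evaluate_accuracy assembles flags and cut-offs per stratum", {
  fix <- four_visit_fixture()
  sep <- fix$wut; sep$wut_count <- c(0L, 0L, 3L, 3L)
  m <- evaluate_accuracy(sep, fix$ref, markers = "USG",
                         strata = tibble::tibble(timepoint = "morning",
                                                 condition = "FL"))
  expect_equal(nrow(m), 3)
  expect_true(all(m$sensitivity == 1 & m$specificity == 1))
  expect_equal(unique(m$cutoff_value), 1.0)  # perfect Youden J
  expect_equal(unique(m$cutoff_k), 3L)       # tie broken toward larger k
  expect_true(all(m$flag_sensitivity & m$flag_specificity))
  expect_equal(unique(m$criterion), "youden")
})
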