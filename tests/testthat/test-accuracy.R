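test_that("classification flags match the inclusive threshold directions", {
  crit <- ase_criteria()
  # high-velocity report: both velocity criteria positive
  hot <- list(v_peak = 4.37, tpg_mean = 50, dvi = 0.2, eoa = 0.7)
  fl <- classify(hot, crit)
  expect_true(fl[["vpeak_ge_3"]] && fl[["vpeak_ge_4"]])
  expect_true(all(fl))
  # healthy-range report: all flags negative
  cold <- list(v_peak = 1.36, tpg_mean = 3.3, dvi = 0.6, eoa = 2.7)
  expect_false(any(classify(cold, crit)))
  # boundary equality counts as positive
  edge <- list(v_peak = 3, tpg_mean = 20, dvi = 0.35, eoa = 1.2)
  fe <- classify(edge, crit)
  expect_true(fe[["vpeak_ge_3"]] && fe[["tpg_ge_20"]] &&
                fe[["dvi_le_0.35"]] && fe[["eoa_le_1.2"]])
  expect_false(fe[["vpeak_ge_4"]] || fe[["dvi_le_0.30"]])
  expect_error(classify(list(v_peak = 3), crit), "missing metric")
})

test_that("ground truth groupings follow the severity definitions", {
  for (d in c(27, 19)) {
    expect_false(ground_truth(case_spec(d, 0, 5), "mild_to_severe"))
    expect_false(ground_truth(case_spec(d, 0, 5), "moderate_to_severe"))
    expect_true(ground_truth(case_spec(d, 50, 5), "mild_to_severe"))
    expect_false(ground_truth(case_spec(d, 50, 5), "moderate_to_severe"))
    expect_true(ground_truth(case_spec(d, 100, 5), "mild_to_severe"))
    expect_true(ground_truth(case_spec(d, 100, 5), "moderate_to_severe"))
  }
  # moderate-to-severe positives are a subset of mild-to-severe positives
  grid <- enumerate_cases()
  mild <- grid$dysfunction_pct %in% c(50, 100)
  mod <- grid$dysfunction_pct == 100
  expect_true(all(!mod | mild))
})

test_that("sensitivity/specificity agrees with brute-force counting on all
           vectors up to length 6", {
  mismatches <- character()
  n_checked <- 0L
  for (n in 1:6) {
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), 2 * n))
    for (r in seq_len(nrow(combos))) {
      flags <- as.logical(combos[r, 1:n])
      labels <- as.logical(combos[r, (n + 1):(2 * n)])
      if (all(labels) || !any(labels)) next
      got <- sensitivity_specificity(flags, labels)
      want <- brute_confusion(flags, labels)
      sw <- sensitivity_specificity(!flags, labels)
      ok <- identical(c(got$tp, got$fp, got$tn, got$fn),
                      c(want$tp, want$fp, want$tn, want$fn)) &&
        isTRUE(all.equal(c(got$sensitivity_pct, got$specificity_pct),
                         c(want$sens, want$spec))) &&
        got$tp + got$fp + got$tn + got$fn == n &&
        # swapping flag polarity swaps the complements
        isTRUE(all.equal(c(sw$sensitivity_pct, sw$specificity_pct),
                         c(100 - got$sensitivity_pct,
                           100 - got$specificity_pct)))
      if (!ok)
        mismatches <- c(mismatches, paste(n, r))
      n_checked <- n_checked + 1L
    }
  }
  expect_identical(mismatches, character())
  expect_gt(n_checked, 3000)
  # degenerate single-class labels are rejected
  expect_error(sensitivity_specificity(c(TRUE, FALSE), c(TRUE, TRUE)),
               "degenerate")
  expect_error(sensitivity_specificity(c(TRUE, FALSE), c(FALSE, FALSE)),
               "degenerate")
})

test_that("worked confusion example and degenerate classifier bounds", {
  ss <- sensitivity_specificity(c(TRUE, FALSE, TRUE, FALSE, FALSE),
                                c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(ss$sensitivity_pct, 50)
  expect_equal(round(ss$specificity_pct, 1), 66.7)
  expect_equal(unlist(ss[c("tp", "fp", "tn", "fn")]),
               c(tp = 1, fp = 1, tn = 2, fn = 1))
  # perfect classifier
  pf <- sensitivity_specificity(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(c(pf$sensitivity_pct, pf$specificity_pct), c(100, 100))
  # all-negative classifier on mixed labels
  an <- sensitivity_specificity(c(FALSE, FALSE, FALSE),
                                c(TRUE, FALSE, TRUE))
  expect_equal(c(an$sensitivity_pct, an$specificity_pct), c(0, 100))
})

test_that("accuracy table covers every criterion and grouping", {
  df <- data.frame(
    dysfunction_pct = c(0, 0, 50, 100, 100, 100),
    lvot_diameter_mm = c(27, 19, 27, 27, 19, 19),
    v_peak = c(1.4, 1.8, 2.5, 3.1, 4.4, 2.9),
    tpg_mean = c(3, 5, 12, 22, 45, 15),
    dvi = c(0.6, 0.8, 0.4, 0.28, 0.26, 0.33),
    eoa = c(2.7, 2.1, 1.8, 1.1, 0.9, 1.3))
  tab <- accuracy_table(df)
  expect_equal(nrow(tab), 9 * 2)
  expect_true(all(tab$sensitivity >= 0 & tab$sensitivity <= 100))
  expect_true(all(tab$tp + tab$fp + tab$tn + tab$fn == nrow(df)))
  # hand count: vpeak >= 3 flags cases 4 and 5; moderate group positives 4:6
  row <- tab[tab$criterion == "vpeak_ge_3" &
               tab$grouping == "moderate_to_severe", ]
  expect_equal(row$tp, 2); expect_equal(row$fn, 1)
  expect_equal(row$sensitivity, 67)
  expect_equal(row$specificity, 100)
  # no negative case crosses a threshold -> specificity 100 for all criteria
  expect_true(all(tab$specificity_exact[tab$fp == 0] == 100))
})

test_that("per-diameter summaries use the n-1 convention and descending
           order", {
  df <- data.frame(
    lvot_diameter_mm = c(27, 27, 19, 19),
    v_peak = c(1, 3, 2, 2), tpg_mean = c(4, 4, 6, 8),
    dvi = c(0.5, 0.5, 0.4, 0.4), eoa = c(2, 2, 1.5, 1.7))
  s <- summarize_by_lvot(df)
  expect_equal(unique(s$lvot_diameter_mm), c(27, 19))
  vp <- s[s$lvot_diameter_mm == 27 & s$metric == "v_peak", ]
  expect_equal(vp$mean, 2)
  expect_equal(vp$sd, sqrt(2), tolerance = 1e-12)
  expect_equal(c(vp$min, vp$max), c(1, 3))
  dv <- s[s$lvot_diameter_mm == 19 & s$metric == "dvi", ]
  expect_equal(dv$sd, 0)
  expect_equal(dv$min, dv$max)
  expect_equal(nrow(s), 2 * 4)
  expect_error(summarize_by_lvot(df[c(1, 3, 4), ]), "fewer than 2")
})
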