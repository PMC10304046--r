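mk_calls <- function(patients, positive) {
  data.frame(patient_id = patients, category = "calcium",
             nlp_use = patients %in% positive, stringsAsFactors = FALSE)
}
mk_survey <- function(patients, positive, category = "calcium") {
  data.frame(patient_id = patients, category = category,
             reported_use = patients %in% positive, stringsAsFactors = FALSE)
}

test_that("confusion counts take the survey as the reference standard", {
  pts <- sprintf("p%02d", 1:10)
  # NLP positive: first three patients; survey positive: first two
  conf <- category_confusion(mk_calls(pts, pts[1:3]),
                             mk_survey(pts, pts[1:2]), "calcium")
  expect_identical(c(conf$tp, conf$fp, conf$fn, conf$tn), c(2L, 1L, 0L, 7L))
  expect_equal(conf$precision, 2 / 3)
  expect_equal(conf$recall, 1)
  expect_equal(conf$prevalence, 0.2)
})

test_that("degenerate confusion tables report NA metrics, not zeros", {
  pts <- sprintf("p%02d", 1:6)
  conf <- category_confusion(mk_calls(pts, character()),
                             mk_survey(pts, character()), "calcium")
  expect_identical(conf$tn, 6L)
  expect_true(is.na(conf$precision))
  expect_true(is.na(conf$recall))
})

test_that("patients outside the survey universe are a hard error", {
  pts <- sprintf("p%02d", 1:4)
  calls <- mk_calls(c(pts, "p99"), "p1")
  expect_error(category_confusion(calls, mk_survey(pts, "p1"), "calcium"),
               "universe mismatch")
})

test_that("micro pooling matches a brute-force single-table computation", {
  set.seed(77)
  pts <- sprintf("p%02d", 1:25)
  cats <- c("calcium", "iron", "tea", "fish oil", "ginseng")
  for (rep in 1:10) {
    calls <- expand.grid(patient_id = pts, category = cats,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    calls$nlp_use <- runif(nrow(calls)) < 0.4
    survey <- expand.grid(patient_id = pts, category = cats,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    survey$reported_use <- runif(nrow(survey)) < 0.5
    rep_out <- agreement_report(calls, survey, prevalence_threshold = 0)
    # brute force: pool every (patient, category) decision into one matrix
    key <- paste(calls$patient_id, calls$category)
    skey <- paste(survey$patient_id, survey$category)
    truth <- survey$reported_use[match(key, skey)]
    tp <- sum(calls$nlp_use & truth)
    fp <- sum(calls$nlp_use & !truth)
    fn <- sum(!calls$nlp_use & truth)
    expect_equal(rep_out$micro_all$precision, tp / (tp + fp))
    expect_equal(rep_out$micro_all$recall, tp / (tp + fn))
    expect_equal(rep_out$micro_all$f1,
                 harmonic_f1(tp / (tp + fp), tp / (tp + fn)))
    # macro is the unweighted mean of the per-category columns
    expect_equal(rep_out$macro_all$f1, mean(rep_out$per_category$f1))
    # and macro is bracketed by the per-category extremes
    expect_gte(rep_out$macro_all$f1, min(rep_out$per_category$f1))
    expect_lte(rep_out$macro_all$f1, max(rep_out$per_category$f1))
  }
})

test_that("macro F1 is the mean of per-category F1, not a harmonic recombination", {
  per <- data.frame(precision = c(0.9, 0.5), recall = c(0.3, 0.9))
  per$f1 <- harmonic_f1(per$precision, per$recall)
  mac <- macro_average(per)
  expect_equal(mac$f1, mean(per$f1))
  expect_false(isTRUE(all.equal(mac$f1,
                                harmonic_f1(mac$precision, mac$recall))))
  # undefined rows are dropped with a warning, not coerced to zero
  per2 <- rbind(per, data.frame(precision = NA_real_, recall = NA_real_,
                                f1 = NA_real_))
  expect_warning(mac2 <- macro_average(per2), "undefined")
  expect_equal(mac2$f1, mac$f1)
})

test_that("the prevalence filter excludes rarely reported categories", {
  pts <- sprintf("p%03d", 1:377)
  # calcium reported by 60/377 (~16%), ginseng by 30/377 (~8%)
  survey <- rbind(mk_survey(pts, pts[1:60], "calcium"),
                  mk_survey(pts, pts[1:30], "ginseng"))
  calls <- rbind(mk_calls(pts, pts[1:50]),
                 data.frame(patient_id = pts, category = "ginseng",
                            nlp_use = pts %in% pts[1:25],
                            stringsAsFactors = FALSE))
  rep_out <- agreement_report(calls, survey, prevalence_threshold = 0.10)
  expect_identical(rep_out$included, "calcium")
  # with a single included category, micro equals macro equals that category
  cal <- rep_out$per_category[rep_out$per_category$category == "calcium", ]
  expect_equal(rep_out$micro$precision, cal$precision)
  expect_equal(rep_out$macro$f1, cal$f1)
  expect_error(agreement_report(calls, survey, prevalence_threshold = 0.99),
               "prevalence threshold")
})
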