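test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- generator_config(n_patients = 8, notes_per_patient = 2, seed = 77,
                          lexicon = LEX)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a$notes, b$notes)
  expect_identical(a$truth_observations, b$truth_observations)
  expect_identical(a$truth_patient_use, b$truth_patient_use)
  # a different seed changes the corpus
  cfg2 <- generator_config(n_patients = 8, notes_per_patient = 2, seed = 78,
                           lexicon = LEX)
  expect_false(identical(generate_corpus(cfg2)$notes$text, a$notes$text))
})

test_that("positive_rate 0 produces an all-negative corpus", {
  cfg <- generator_config(n_patients = 6, notes_per_patient = 2,
                          positive_rate = 0, seed = 5, lexicon = LEX)
  co <- generate_corpus(cfg)
  expect_true(all(co$truth_observations$label == "no"))
  expect_false(any(co$truth_patient_use$used))
})

test_that("ground-truth occurrences coincide with the matcher on emitted text", {
  cfg <- generator_config(n_patients = 10, notes_per_patient = 3, seed = 19,
                          lexicon = LEX)
  co <- generate_corpus(cfg)
  for (i in seq_len(nrow(co$notes))) {
    m <- match_keywords(tokenize(co$notes$text[i]), LEX)
    tr <- co$truth_observations[co$truth_observations$note_id ==
                                  co$notes$note_id[i], ]
    expect_identical(m$token_index, tr$token_index)
    expect_identical(m$keyword, tr$keyword)
    expect_identical(m$category, tr$category)
  }
  # patient-level truth is any-positive per category
  pos <- unique(co$truth_observations[co$truth_observations$label == "yes",
                                      c("patient_id", "category")])
  tru <- co$truth_patient_use
  expect_identical(tru$used,
                   paste(tru$patient_id, tru$category) %in%
                     paste(pos$patient_id, pos$category))
})

test_that("note dates fall inside the survey-anchored window", {
  cfg <- generator_config(n_patients = 10, notes_per_patient = 4, seed = 3,
                          lexicon = LEX)
  co <- generate_corpus(cfg)
  expect_identical(nrow(filter_notes(co$notes, cfg$survey_date)),
                   nrow(co$notes))
})

test_that("zero-discordance surveys equal the ground truth exactly", {
  cfg <- generator_config(n_patients = 10, notes_per_patient = 2, seed = 8,
                          lexicon = LEX)
  co <- generate_corpus(cfg)
  sv <- generate_survey(co$truth_patient_use, cfg)
  expect_identical(sv$reported_use, co$truth_patient_use$used)
  expect_identical(sv$patient_id, co$truth_patient_use$patient_id)
  # reproducible independently of corpus generation
  expect_identical(sv, generate_survey(co$truth_patient_use, cfg))
})

test_that("full under-reporting flips every prescribed-style positive", {
  cfg <- generator_config(
    n_patients = 20, notes_per_patient = 3, seed = 4, lexicon = LEX,
    survey_discordance = list(underreport_prescribed = 1, overreport = 0))
  co <- generate_corpus(cfg)
  sv <- generate_survey(co$truth_patient_use, cfg)
  presc <- co$truth_patient_use$category %in% cfg$prescribed_categories
  used <- co$truth_patient_use$used
  expect_false(any(sv$reported_use[presc & used]))
  expect_identical(sv$reported_use[!presc], used[!presc])
})

test_that("the under-reporting rate is respected within its binomial bounds", {
  cfg <- generator_config(
    seed = 12, lexicon = LEX,
    survey_discordance = list(underreport_prescribed = 0.5, overreport = 0))
  # a hand-built truth table: 600 patients all truly using folic acid,
  # plus an unaffected non-prescribed category
  truth <- rbind(
    data.frame(patient_id = sprintf("p%03d", 1:600), category = "folic acid",
               used = TRUE, stringsAsFactors = FALSE),
    data.frame(patient_id = sprintf("p%03d", 1:600), category = "garlic",
               used = TRUE, stringsAsFactors = FALSE)
  )
  sv <- generate_survey(truth, cfg)
  expect_true(all(sv$reported_use[sv$category == "garlic"]))
  presc <- truth$category %in% cfg$prescribed_categories
  used <- truth$used
  n <- sum(presc & used)
  expect_gte(n, 500)
  flipped <- sum(!sv$reported_use[presc & used])
  # exact binomial 99% interval around rate 0.5
  expect_gte(flipped, qbinom(0.005, n, 0.5))
  expect_lte(flipped, qbinom(0.995, n, 0.5))
})

test_that("impossible configurations are rejected", {
  expect_error(generator_config(positive_rate = 1.2), "positive_rate")
  expect_error(generator_config(
    survey_discordance = list(underreport_prescribed = -0.1, overreport = 0)))
  expect_error(generator_config(template_mix = c(bogus_family = 1)),
               "template families")
  mix0 <- c(active_list = 0, asterisk_list = 0, narrative = 0,
            allergy = 1, lab = 1, food = 1, compound = 1)
  expect_error(generator_config(template_mix = mix0, positive_rate = 0.5),
               "impossible config")
  expect_silent(generator_config(template_mix = mix0, positive_rate = 0))
})

test_that("every generator surface resolves to its intended category", {
  surfaces <- suppuse:::.category_surfaces
  for (cat in names(surfaces)) {
    for (s in surfaces[[cat]]) {
      m <- match_keywords(tokenize(toupper(s)), LEX)
      expect_gte(nrow(m), 1)
      expect_true(all(m$category == cat),
                  info = paste("surface:", s, "->", cat))
    }
  }
})
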