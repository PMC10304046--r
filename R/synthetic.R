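# Synthetic clinical-note and survey generator with known ground truth.
# Notes are assembled from template families that emulate the
# phenomenology of semi-structured VA-style notes: numbered active-med
# lists, asterisk-run med lists, and narrative current use (positive
# families); all-caps allergy lines, chemistry panels with keyword
# homonyms (creatinine/calcium/potassium), food and diet mentions, and
# compound drug names (atorvastatin calcium, losartan potassium)
# (negative families). Every keyword occurrence carries a ground-truth
# yes/no label; patient-level truth is any-positive per category.

# Surface forms the generator may emit for each category. Every surface
# tokenizes to at least one lexicon keyword that resolves to the intended
# category (validated in tests); surrounding template words never collide
# with lexicon keywords.
.category_surfaces <- list(
  "aloe vera" = c("aloe vera", "aloe"),
  "astragalus" = "astragalus",
  "biotin" = "biotin",
  "calcium" = c("calcium", "calcium citrate"),
  "chondroitin" = c("chondroitin", "chondroitin sulfate"),
  "cinnamon" = "cinnamon",
  "coenzyme q10" = "coenzyme q10",
  "cranberry" = c("cranberry", "cranberry extract"),
  "creatine" = "creatine",
  "curcumin" = c("turmeric", "tumeric"),
  "dhea" = "dhea",
  "digitalis" = "digitalis",
  "echinacea" = "echinacea",
  "fiber" = c("fiber", "fiber powder"),
  "fish oil" = c("fish oil", "fishoil", "krill oil"),
  "folic acid" = "folic acid",
  "garlic" = c("garlic", "garlic extract"),
  "ginger" = c("ginger", "ginger root"),
  "ginkgo biloba" = c("ginkgo biloba", "ginko"),
  "ginseng" = "ginseng",
  "glucosamine" = "glucosamine",
  "iron" = c("iron", "iron sulfate"),
  "licorice" = c("licorice", "licorice root"),
  "magnesium" = c("magnesium", "magnesium oxide"),
  "melatonin" = "melatonin",
  "multivitamin" = c("multivitamin", "multivitamins"),
  "oregano" = c("oregano oil",  "oregano"),
  "palmetto" = "saw palmetto",
  "potassium" = c("potassium", "potasium"),
  "probiotic" = c("acidophilus", "lactobacillus acidophilus"),
  "tea" = c("green tea", "tea"),
  "thiamine" = c("thiamine", "thiamin"),
  "thistle" = "milk thistle",
  "vitamin a" = "vitamin a",
  "vitamin b12" = c("vitamin b12", "cyanocobalamin"),
  "vitamin b2" = c("vitamin b2", "riboflavin"),
  "vitamin b3" = c("vitamin b3", "niacin"),
  "vitamin b6" = c("vitamin b6", "pyridoxine"),
  "vitamin c" = "vitamin c",
  "vitamin d2" = c("vitamin d2", "ergocalciferol"),
  "vitamin d3" = c("vitamin d3", "cholecalciferol", "vitd"),
  "willow" = "willow bark",
  "yeast" = "brewers yeast",
  "zinc" = c("zinc", "zinc gluconate")
)

.pos_families <- c("active_list", "asterisk_list", "narrative")
.neg_families <- c("allergy", "lab", "food", "compound")

.filler_drugs <- c("OMEPRAZOLE", "LISINOPRIL", "METFORMIN", "ATENOLOL",
                   "AMLODIPINE", "GABAPENTIN", "SERTRALINE", "ASPIRIN")
.filler_sentences <- c(
  "Vital signs stable today.",
  "Follow up in 3 months with primary care.",
  "Patient ambulating without assistance.",
  "Reviewed current medication list with patient.",
  "No acute distress noted on exam.",
  "Discussed exercise goals and sleep hygiene."
)
.doses <- c("500MG", "1000 UNT", "5MG", "400MG", "1 TAB")
.freqs <- c("QDAY", "BID", "QHS", "DAILY")
.reasons <- c("sleep", "joint pain", "bone health", "heart health",
              "memory", "immune support", "general wellness")

# negative-capable surfaces per family (surface, shown as emitted)
.neg_surfaces <- list(
  allergy = c("NIACIN", "FISH", "IRON", "GARLIC", "ECHINACEA"),
  lab = c("creatinine", "calcium", "potassium", "magnesium"),
  food = c("fish", "ginger", "cinnamon", "garlic", "tea"),
  compound = c("calcium", "potassium", "zinc")
)
.lab_ranges <- list(creatinine = c(0.6, 1.4), calcium = c(8.0, 10.2),
                    potassium = c(3.5, 5.1), magnesium = c(1.5, 2.3))

#' Configuration for the synthetic note/survey generator
#'
#' Defaults encode the study conditions being emulated: 377 survey
#' participants, 58\% of keyword occurrences indicating active use, a
#' one-year-back / one-month-forward note window around a common survey
#' date, and zero self-report discordance (the discordance rates are the
#' experimental dials).
#'
#' @param n_patients Number of patients (default 377).
#' @param notes_per_patient Notes generated per patient (default 5).
#' @param positive_rate Probability that a keyword segment is drawn from a
#'   positive (active-use) template family (default 0.58).
#' @param template_mix Named non-negative weights over the seven template
#'   families \code{active_list}, \code{asterisk_list}, \code{narrative}
#'   (positive) and \code{allergy}, \code{lab}, \code{food},
#'   \code{compound} (negative). Renormalised within each sign.
#' @param survey_discordance List with rates \code{underreport_prescribed}
#'   (probability a true use of a prescribed-style category is reported
#'   "no" on the survey) and \code{overreport} (probability a non-use is
#'   reported "yes"). Both default 0.
#' @param prescribed_categories Categories subject to under-reporting
#'   (default folic acid, melatonin, multivitamin — items commonly
#'   physician-prescribed and hence often not regarded as "supplements").
#' @param categories_per_patient Integer range (min, max) of supplement
#'   categories each patient actively uses (default 2..8).
#' @param segments_per_note Integer range of keyword-bearing segments per
#'   note (default 3..6).
#' @param survey_date Common survey date (default "2016-06-15").
#' @param patient_prefix Prefix for generated patient ids.
#' @param seed Integer RNG seed; identical config + seed gives a
#'   byte-identical corpus.
#' @param lexicon A \code{supp_lexicon}.
#' @return A validated list of class \code{supp_genconfig}.
#' @export
generator_config <- function(n_patients = 377L,
                             notes_per_patient = 5L,
                             positive_rate = 0.58,
                             template_mix = NULL,
                             survey_discordance = list(underreport_prescribed = 0,
                                                       overreport = 0),
                             prescribed_categories = c("folic acid", "melatonin",
                                                       "multivitamin"),
                             categories_per_patient = c(2L, 8L),
                             segments_per_note = c(3L, 6L),
                             survey_date = as.Date("2016-06-15"),
                             patient_prefix = "P",
                             seed = 1L,
                             lexicon = load_lexicon()) {
  fams <- c(.pos_families, .neg_families)
  if (is.null(template_mix)) {
    template_mix <- stats::setNames(rep(1 / length(fams), length(fams)), fams)
  }
  if (is.null(names(template_mix)) || !all(names(template_mix) %in% fams) ||
      anyDuplicated(names(template_mix))) {
    stop("template_mix must be named with the template families: ",
         paste(fams, collapse = ", "))
  }
  mix <- stats::setNames(rep(0, length(fams)), fams)
  mix[names(template_mix)] <- template_mix
  if (any(mix < 0) || sum(mix) <= 0) stop("template_mix weights must be non-negative and not all zero")
  mix <- mix / sum(mix)
  u <- survey_discordance$underreport_prescribed %||% 0
  o <- survey_discordance$overreport %||% 0
  stopifnot(n_patients >= 1L, notes_per_patient >= 1L,
            positive_rate >= 0, positive_rate <= 1,
            u >= 0, u <= 1, o >= 0, o <= 1,
            length(categories_per_patient) == 2L,
            categories_per_patient[1L] >= 1L,
            categories_per_patient[2L] >= categories_per_patient[1L],
            length(segments_per_note) == 2L, segments_per_note[1L] >= 1L,
            segments_per_note[2L] >= segments_per_note[1L])
  if (positive_rate > 0 && sum(mix[.pos_families]) <= 0) {
    stop("impossible config: positive_rate > 0 but no positive template family has weight")
  }
  if (positive_rate < 1 && sum(mix[.neg_families]) <= 0) {
    stop("impossible config: positive_rate < 1 but no negative template family has weight")
  }
  structure(list(n_patients = as.integer(n_patients),
                 notes_per_patient = as.integer(notes_per_patient),
                 positive_rate = positive_rate, template_mix = mix,
                 survey_discordance = list(underreport_prescribed = u,
                                           overreport = o),
                 prescribed_categories = prescribed_categories,
                 categories_per_patient = as.integer(categories_per_patient),
                 segments_per_note = as.integer(segments_per_note),
                 survey_date = as.Date(survey_date),
                 patient_prefix = patient_prefix,
                 seed = as.integer(seed), lexicon = lexicon),
            class = "supp_genconfig")
}

.pick <- function(x) if (length(x) == 1L) x else x[[sample.int(length(x), 1L)]]

.render_positive <- function(family, category) {
  surf <- .pick(.category_surfaces[[category]])
  switch(family,
    active_list = sprintf("(%d) %s %s %s ACTIVE Give: %s PO %s",
                          sample.int(30L, 1L), toupper(surf), .pick(.doses),
                          .pick(c("TAB", "CAP", "CAP/TAB")), .pick(.doses),
                          .pick(.freqs)),
    asterisk_list = sprintf("*%s %s po %s*%s %s po %s*%s %s po %s",
                            .pick(.filler_drugs), .pick(.doses), .pick(.freqs),
                            surf, .pick(.doses), .pick(.freqs),
                            .pick(.filler_drugs), .pick(.doses), .pick(.freqs)),
    narrative = .pick(c(
      sprintf("Patient reports taking %s %s for %s.", surf,
              .pick(c("daily", "twice daily", "every night", "most days")),
              .pick(.reasons)),
      sprintf("Continues %s daily with good effect.", surf),
      sprintf("Currently on %s for %s.", surf, .pick(.reasons)),
      sprintf("Takes %s purchased over the counter for %s.", surf,
              .pick(.reasons))
    )),
    stop("unknown positive family: ", family))
}

.render_negative <- function(family) {
  switch(family,
    allergy = {
      surf <- .pick(.neg_surfaces$allergy)
      .pick(c(sprintf("ALLERGIES: %s, %s",
                      .pick(c("PENICILLIN", "SULFA", "LATEX", "CODEINE")), surf),
              sprintf("ALLERGIC REACTIONS: %s (%s)", surf,
                      .pick(c("RASH", "HIVES", "NAUSEA")))))
    },
    lab = {
      surf <- .pick(.neg_surfaces$lab)
      r <- .lab_ranges[[surf]]
      val <- sprintf("%.1f", stats::runif(1L, r[1L], r[2L]))
      .pick(c(sprintf("Chemistry shows a glucose of %d and %s of %s.",
                      sample(80:180, 1L), surf, val),
              sprintf("Labs: sodium %d, %s %s, glucose %d.",
                      sample(135:145, 1L), surf, val, sample(80:180, 1L)),
              sprintf("%s%s stable at %s, renal panel otherwise at baseline.",
                      toupper(substr(surf, 1L, 1L)), substr(surf, 2L, nchar(surf)),
                      val)))
    },
    food = {
      surf <- .pick(.neg_surfaces$food)
      switch(surf,
        fish = "Lunch group today shared baked fish, rice, and mixed vegetables.",
        ginger = "Advised clear liquids such as ginger ale or broth as tolerated.",
        cinnamon = "Patient enjoyed cinnamon rolls at the canteen with family.",
        garlic = "Dinner menu included pasta with garlic bread.",
        tea = "Offered iced tea and juice during the visit.")
    },
    compound = .pick(c(
      sprintf("ATORVASTATIN CALCIUM %dMG TAB Give: 1 TAB PO QPM", .pick(c(20L, 40L, 80L))),
      "LOSARTAN POTASSIUM 50MG TAB Give: 1 TAB PO QDAY",
      "ZINC OXIDE OINTMENT APPLY TO AFFECTED AREA TWICE DAILY",
      "DOCUSATE CALCIUM 240MG CAP Give: 1 CAP PO BID")),
    stop("unknown negative family: ", family))
}

#' Generate a synthetic note corpus with ground truth
#'
#' Assembles notes from the template families described in
#' [generator_config()]. Every lexicon keyword occurrence in the emitted
#' text carries a ground-truth label ("yes" = the mention indicates active
#' supplement use); patient-level truth is any-positive per category. The
#' generator verifies at run time that the whole-document keyword matches
#' equal the per-segment matches it planned, so templates cannot create
#' unlabeled accidental keyword collisions.
#'
#' @param config A [generator_config()].
#' @return List with \code{notes} (data.frame \code{note_id},
#'   \code{patient_id}, \code{note_date}, \code{text}),
#'   \code{truth_observations} (\code{note_id}, \code{patient_id},
#'   \code{token_index}, \code{keyword}, \code{category}, \code{label}),
#'   \code{truth_patient_use} (\code{patient_id}, \code{category},
#'   \code{used}; full patient-by-category grid) and \code{config}.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "supp_genconfig"))
  set.seed(config$seed)
  lex <- config$lexicon
  cats <- names(.category_surfaces)
  cats <- cats[cats %in% lex$categories]
  pos_mix <- config$template_mix[.pos_families]
  neg_mix <- config$template_mix[.neg_families]
  pids <- sprintf("%s%04d", config$patient_prefix, seq_len(config$n_patients))
  notes_list <- vector("list", config$n_patients * config$notes_per_patient)
  truth_list <- vector("list", length(notes_list))
  ni <- 0L
  for (p in seq_along(pids)) {
    pid <- pids[[p]]
    n_use <- sample(config$categories_per_patient[1L]:config$categories_per_patient[2L], 1L)
    used <- sample(cats, min(n_use, length(cats)))
    for (j in seq_len(config$notes_per_patient)) {
      ni <- ni + 1L
      note_id <- sprintf("%s-%02d", pid, j)
      note_date <- config$survey_date + sample(-365L:30L, 1L)
      n_seg <- sample(config$segments_per_note[1L]:config$segments_per_note[2L], 1L)
      segs <- character(n_seg)
      seg_lab <- character(n_seg)
      for (s in seq_len(n_seg)) {
        if (stats::runif(1L) < config$positive_rate) {
          fam <- sample(.pos_families, 1L, prob = pos_mix)
          segs[[s]] <- .render_positive(fam, .pick(used))
          seg_lab[[s]] <- "yes"
        } else {
          fam <- sample(.neg_families, 1L, prob = neg_mix)
          segs[[s]] <- .render_negative(fam)
          seg_lab[[s]] <- "no"
        }
      }
      n_fill <- sample(1:3, 1L)
      fills <- sample(.filler_sentences, n_fill)
      all_segs <- c(segs, fills)
      all_labs <- c(seg_lab, rep(NA_character_, n_fill))
      ord <- sample.int(length(all_segs))
      all_segs <- all_segs[ord]
      all_labs <- all_labs[ord]
      text <- paste(all_segs, collapse = "\n")
      # plan the truth rows segment by segment, then verify on the whole doc
      offset <- 0L
      rows <- vector("list", length(all_segs))
      for (s in seq_along(all_segs)) {
        toks <- tokenize(all_segs[[s]])
        m <- match_keywords(toks, lex)
        if (nrow(m) > 0L) {
          if (is.na(all_labs[[s]])) {
            stop("template collision: filler segment contains a lexicon keyword: ",
                 all_segs[[s]])
          }
          rows[[s]] <- data.frame(note_id = note_id, patient_id = pid,
                                  token_index = offset + m$token_index,
                                  keyword = m$keyword, category = m$category,
                                  label = all_labs[[s]],
                                  stringsAsFactors = FALSE)
        }
        offset <- offset + length(toks)
      }
      planned <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
      check <- match_keywords(tokenize(text), lex)
      if (is.null(planned)) planned <- data.frame(token_index = integer(), keyword = character())
      if (nrow(check) != nrow(planned) ||
          !identical(check$token_index, planned$token_index) ||
          !identical(check$keyword, planned$keyword)) {
        stop("template collision: document-level keyword matches differ from planned matches in ", note_id)
      }
      notes_list[[ni]] <- data.frame(note_id = note_id, patient_id = pid,
                                     note_date = note_date, text = text,
                                     stringsAsFactors = FALSE)
      truth_list[[ni]] <- if (nrow(planned)) planned else NULL
    }
  }
  notes <- do.call(rbind, notes_list)
  truth <- do.call(rbind, truth_list[!vapply(truth_list, is.null, TRUE)])
  rownames(notes) <- rownames(truth) <- NULL
  pos <- unique(truth[truth$label == "yes", c("patient_id", "category")])
  grid <- expand.grid(category = lex$categories, patient_id = pids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$used <- paste(grid$patient_id, grid$category) %in%
    paste(pos$patient_id, pos$category)
  truth_use <- grid[order(grid$patient_id, grid$category),
                    c("patient_id", "category", "used")]
  rownames(truth_use) <- NULL
  list(notes = notes, truth_observations = truth,
       truth_patient_use = truth_use, config = config)
}

#' Generate survey self-report from patient-level ground truth
#'
#' Starts from true patient-level use and injects controllable
#' discordance: true use of a prescribed-style category is reported "no"
#' with rate \code{underreport_prescribed} (patients often do not regard
#' physician-prescribed items as supplements), and non-use is reported
#' "yes" with rate \code{overreport}. Deterministic for a given config
#' seed (an RNG stream derived from \code{config$seed} is used, so corpus
#' and survey generation are independently reproducible).
#'
#' @param truth_patient_use Data.frame \code{patient_id}, \code{category},
#'   \code{used} from [generate_corpus()].
#' @param config The same [generator_config()].
#' @return Survey data.frame: \code{patient_id}, \code{survey_date},
#'   \code{category}, \code{reported_use}.
#' @export
generate_survey <- function(truth_patient_use, config) {
  stopifnot(inherits(config, "supp_genconfig"),
            all(c("patient_id", "category", "used") %in% names(truth_patient_use)))
  set.seed(config$seed + 10007L)
  u <- config$survey_discordance$underreport_prescribed
  o <- config$survey_discordance$overreport
  used <- as.logical(truth_patient_use$used)
  presc <- truth_patient_use$category %in% config$prescribed_categories
  r <- stats::runif(length(used))
  reported <- used
  reported[used & presc & r < u] <- FALSE
  reported[!used & r < o] <- TRUE
  data.frame(patient_id = truth_patient_use$patient_id,
             survey_date = config$survey_date,
             category = truth_patient_use$category,
             reported_use = reported, stringsAsFactors = FALSE)
}
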