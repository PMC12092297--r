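#' Simulate a paired symptom/feature longitudinal panel
#'
#' Draws data directly from the bivariate random-intercept model that
#' [fit_blmm()] estimates: per participant a correlated pair of random
#' intercepts (correlation `rho_b`), per occasion a correlated pair of
#' residuals (correlation `rho_w`), plus an optional occasion-specific
#' symptom trend. This is the working horse for calibration and
#' operating-characteristic studies where the ground truth must be exact.
#'
#' @param n_participants number of participants.
#' @param timepoints integer count of occasions, or a strictly increasing
#'   vector of day offsets.
#' @param rho_b,rho_w planted between- and within-subject correlations in
#'   \[-1, 1\] (the boundary values produce degenerate but valid draws).
#' @param sd_b,sd_w length-2 standard deviations (symptom, feature) of the
#'   random intercepts and occasion residuals.
#' @param mu length-2 grand means (symptom, feature).
#' @param trend per-occasion symptom mean offsets; default none.
#' @param missing_rate probability that each observed cell (symptom or
#'   feature, independently) is deleted, missing completely at random.
#' @param seed integer seed; identical seeds give identical panels.
#' @return data frame (`participant_id`, `timepoint_day`, `symptom`,
#'   `feature`) with the latent draws attached as `attr(, "truth")`.
#' @export
simulate_blmm_panel <- function(n_participants, timepoints,
                                rho_b = 0.3, rho_w = 0.15,
                                sd_b = c(1, 1), sd_w = c(1, 1),
                                mu = c(0, 0), trend = NULL,
                                missing_rate = 0, seed = 1) {
  stopifnot(n_participants >= 1, abs(rho_b) <= 1, abs(rho_w) <= 1,
            missing_rate >= 0, missing_rate <= 1)
  tps <- if (length(timepoints) == 1) seq_len(timepoints) else timepoints
  if (any(diff(tps) <= 0)) stop_("timepoints must be strictly increasing")
  Tn <- length(tps)
  if (is.null(trend)) trend <- rep(0, Tn)
  stopifnot(length(trend) == Tn)
  with_local_seed(seed, {
    n <- n_participants
    b_s <- stats::rnorm(n)
    b_f <- rho_b * b_s + sqrt(1 - rho_b^2) * stats::rnorm(n)
    e_s <- matrix(stats::rnorm(n * Tn), n, Tn)
    e_f <- rho_w * e_s + sqrt(1 - rho_w^2) * matrix(stats::rnorm(n * Tn), n, Tn)
    s <- mu[1] + rep(trend, each = n) + sd_b[1] * b_s + sd_w[1] * e_s
    f <- mu[2] + sd_b[2] * b_f + sd_w[2] * e_f
    if (missing_rate > 0) {
      s[stats::runif(n * Tn) < missing_rate] <- NA
      f[stats::runif(n * Tn) < missing_rate] <- NA
    }
    panel <- data.frame(
      participant_id = rep(sprintf("P%04d", seq_len(n)), Tn),
      timepoint_day = rep(tps, each = n),
      symptom = as.vector(s), feature = as.vector(f))
    attr(panel, "truth") <- list(rho_b = rho_b, rho_w = rho_w,
                                 b_s = b_s, b_f = b_f, e_s = e_s, e_f = e_f)
    panel
  })
}

#' Configuration for the synthetic smartphone cohort
#'
#' Bundles and validates every knob of [simulate_cohort()]. Defaults emulate
#' the study design the pipeline targets: flash surveys at ten timepoints
#' spanning days 7–180 with a declining median severity trajectory,
#' planned-missing item responses, and daily word bags whose category
#' composition tracks a latent language-feature value.
#'
#' @param n_participants cohort size.
#' @param timepoints strictly increasing survey day offsets.
#' @param n_features number of latent language features (each tied to one
#'   word category of the built-in vocabulary).
#' @param planted_pairs list of `list(feature, domain, rho_b, rho_w)`
#'   entries; a feature index may appear in at most one pair. All other
#'   feature/domain combinations are null.
#' @param latent_trend per-timepoint mean severity offsets (default a linear
#'   decline, matching improvement over follow-up).
#' @param item_loadings list, one numeric vector of factor loadings per
#'   symptom domain (length = items for that domain).
#' @param item_noise_sd multiplier on the item uniquenesses
#'   (`sqrt(1 - lambda^2) * item_noise_sd`).
#' @param missing_rate_survey,missing_rate_words probabilities in \[0,1\]:
#'   item responses dropped, and whole word-bag days dropped.
#' @param missing_mode `"MCAR"` (default; the study's missingness diagnostic
#'   supports ignorability) or `"MAR"`, which links dropout to current
#'   severity with strength `mar_strength` on the logit scale.
#' @param words_per_day_mean mean words typed per retained day.
#' @param icc share of unit latent variance that is between-participant,
#'   for both severities and features.
#' @param softmax_beta slope of the log-linear link from the latent feature
#'   value to its word category's emission weight.
#' @param os_switch_rate fraction of participants whose device log shows an
#'   operating-system switch within follow-up.
#' @param extra_days word-bag days per participant beyond the
#'   survey-adjacent (day-before/day-of) days.
#' @param ar_rho optional lag-1 autocorrelation of occasion residuals
#'   (default 0, matching the fitted model; nonzero values exist to probe
#'   misspecification).
#' @param origin_date calendar date of day 0 (ISO-8601 string).
#' @param seed master seed; all internal streams derive from it by fixed
#'   offsets, so e.g. adding features does not perturb the survey draws.
#' @return validated `sim_config` object (a list).
#' @export
sim_config <- function(n_participants = 200,
                       timepoints = c(7, 21, 35, 49, 63, 84, 105, 126, 154, 180),
                       n_features = 6,
                       planted_pairs = list(list(feature = 1, domain = 1,
                                                 rho_b = 0.3, rho_w = 0.15)),
                       latent_trend = NULL,
                       item_loadings = rep(list(c(0.8, 0.7, 0.6)), 10),
                       item_noise_sd = 1,
                       missing_rate_survey = 0.15,
                       missing_rate_words = 0.2,
                       missing_mode = c("MCAR", "MAR"),
                       mar_strength = 0.5,
                       words_per_day_mean = 300,
                       icc = 0.55,
                       softmax_beta = 0.4,
                       os_switch_rate = 0.02,
                       extra_days = 5,
                       ar_rho = 0,
                       origin_date = "2020-01-01",
                       seed = 1) {
  missing_mode <- match.arg(missing_mode)
  if (n_participants < 1) stop_("n_participants must be a positive integer")
  if (any(diff(timepoints) <= 0)) stop_("timepoints must be strictly increasing")
  n_domains <- length(item_loadings)
  if (is.null(latent_trend))
    latent_trend <- seq(0.6, -0.6, length.out = length(timepoints))
  stopifnot(length(latent_trend) == length(timepoints))
  vocab <- lm_default_vocab()
  if (n_features > length(vocab$categories))
    stop_("n_features cannot exceed the %d built-in word categories",
          length(vocab$categories))
  seen <- integer(0)
  for (pp in planted_pairs) {
    stopifnot(all(c("feature", "domain", "rho_b", "rho_w") %in% names(pp)))
    if (abs(pp$rho_b) > 1 || abs(pp$rho_w) > 1)
      stop_("planted correlations must lie in [-1, 1]")
    if (abs(pp$rho_b) > 1 - 1e-12 || abs(pp$rho_w) > 1 - 1e-12) {
      # boundary allowed: degenerate (rank-1) implied covariance
    }
    if (pp$feature > n_features || pp$domain > n_domains)
      stop_("planted pair indexes a feature or domain that does not exist")
    if (pp$feature %in% seen)
      stop_("feature %d appears in more than one planted pair", pp$feature)
    seen <- c(seen, pp$feature)
  }
  stopifnot(item_noise_sd > 0, words_per_day_mean > 0,
            missing_rate_survey >= 0, missing_rate_survey <= 1,
            missing_rate_words >= 0, missing_rate_words <= 1,
            icc > 0, icc < 1)
  structure(list(
    n_participants = n_participants, timepoints = timepoints,
    n_features = n_features, n_domains = n_domains,
    planted_pairs = planted_pairs, latent_trend = latent_trend,
    item_loadings = item_loadings, item_noise_sd = item_noise_sd,
    missing_rate_survey = missing_rate_survey,
    missing_rate_words = missing_rate_words,
    missing_mode = missing_mode, mar_strength = mar_strength,
    words_per_day_mean = words_per_day_mean, icc = icc,
    softmax_beta = softmax_beta, os_switch_rate = os_switch_rate,
    extra_days = extra_days, ar_rho = ar_rho,
    origin_date = origin_date, seed = seed
  ), class = "sim_config")
}

# Built-in word categories mirroring the shipped toy lexicons, plus filler
# vocabulary. Generator emissions are drawn from these lists so the lexicon
# stage recovers the planted category signal.
lm_default_vocab <- function() {
  categories <- list(
    pronoun_i = c("i", "me", "my", "mine", "myself"),
    social    = c("friend", "family", "people", "talked", "talking", "mom", "dad"),
    negemo    = c("sad", "angry", "hurt", "hurting", "afraid", "crying", "hate"),
    posemo    = c("happy", "good", "loved", "love", "great", "nice"),
    health    = c("ill", "illness", "sick", "pain", "painful", "aches", "doctor", "tired"),
    cognitive = c("think", "thinking", "know", "because", "reasons", "wondering")
  )
  filler <- c("the", "and", "to", "a", "of", "in", "day", "work", "home",
              "food", "dog", "car", "phone", "time", "go", "get", "see",
              "now", "later", "ok", "yes", "week", "today", "tomorrow")
  list(categories = categories, filler = filler)
}

#' Simulate a full synthetic cohort: word bags, survey items, side tables
#'
#' Generates every input stream the pipeline consumes, with known ground
#' truth. Latent severity for domain \eqn{d} follows the random-intercept
#' model \eqn{\eta_{ijd} = trend_j + b_{id} + e_{ijd}}; latent feature
#' values follow the matching model; for each planted pair the intercepts
#' and residuals are drawn with the configured correlations. Survey items
#' load on the latent severity through a one-factor measurement model, and
#' word bags are multinomial draws whose category emission weights follow a
#' log-linear (softmax) link in the latent feature value on the
#' survey-adjacent days.
#'
#' @param config a [sim_config()] object.
#' @return list of class `lm_cohort` with elements `word_bags`,
#'   `survey_items`, `schedule`, `device_log`, `completion`, `domain_spec`,
#'   `truth` (ground truth; never an analysis input), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  n <- cf$n_participants
  tps <- cf$timepoints
  Tn <- length(tps)
  nF <- cf$n_features
  nD <- cf$n_domains
  ids <- sprintf("P%04d", seq_len(n))
  origin <- as.Date(cf$origin_date)
  sd_b <- sqrt(cf$icc); sd_w <- sqrt(1 - cf$icc)

  # planted-pair lookup: feature index -> (domain, rho_b, rho_w)
  plant <- list()
  for (pp in cf$planted_pairs) plant[[as.character(pp$feature)]] <- pp

  ## Stream 1: latent severities and features -------------------------------
  lat <- with_local_seed(cf$seed + 1L, {
    b_dom <- matrix(stats::rnorm(n * nD), n, nD)
    e_dom <- array(stats::rnorm(n * Tn * nD), c(n, Tn, nD))
    if (cf$ar_rho != 0) {  # optional serial correlation hook
      for (j in 2:Tn) e_dom[, j, ] <- cf$ar_rho * e_dom[, j - 1L, ] +
          sqrt(1 - cf$ar_rho^2) * e_dom[, j, ]
    }
    b_feat <- matrix(stats::rnorm(n * nF), n, nF)
    e_feat <- array(stats::rnorm(n * Tn * nF), c(n, Tn, nF))
    for (fi in seq_len(nF)) {
      pp <- plant[[as.character(fi)]]
      if (!is.null(pp)) {
        d <- pp$domain
        b_feat[, fi] <- pp$rho_b * b_dom[, d] +
          sqrt(1 - pp$rho_b^2) * b_feat[, fi]
        e_feat[, , fi] <- pp$rho_w * e_dom[, , d] +
          sqrt(1 - pp$rho_w^2) * e_feat[, , fi]
      }
    }
    eta <- array(0, c(n, Tn, nD))
    for (d in seq_len(nD))
      eta[, , d] <- rep(cf$latent_trend, each = n) +
        sd_b * b_dom[, d] + sd_w * e_dom[, , d]
    z <- array(0, c(n, Tn, nF))
    for (fi in seq_len(nF))
      z[, , fi] <- sd_b * b_feat[, fi] + sd_w * e_feat[, , fi]
    list(eta = eta, z = z, b_dom = b_dom, b_feat = b_feat)
  })

  ## Stream 2: survey items --------------------------------------------------
  survey <- with_local_seed(cf$seed + 2L, {
    rows <- vector("list", nD)
    for (d in seq_len(nD)) {
      lam <- cf$item_loadings[[d]]
      K <- length(lam)
      th <- pmax(1 - lam^2, 1e-6)
      val <- matrix(0, n * Tn, K)
      eta_vec <- as.vector(lat$eta[, , d])
      for (k in seq_len(K))
        val[, k] <- lam[k] * eta_vec +
          cf$item_noise_sd * sqrt(th[k]) * stats::rnorm(n * Tn)
      rows[[d]] <- data.frame(
        participant_id = rep(rep(ids, Tn), K),
        timepoint_day = rep(rep(tps, each = n), K),
        item_id = rep(sprintf("d%02d_i%d", d, seq_len(K)), each = n * Tn),
        value = as.vector(val))
    }
    do.call(rbind, rows)
  })

  ## Stream 3: word bags ------------------------------------------------------
  vocab <- lm_default_vocab()
  cat_words <- vocab$categories[seq_len(nF)]
  all_words <- c(unlist(cat_words, use.names = FALSE), vocab$filler)
  word_cat <- rep(c(seq_len(nF), 0L),
                  c(lengths(cat_words), length(vocab$filler)))
  # fixed Zipf-like within-category word weights
  wgt_within <- unlist(lapply(c(lengths(cat_words), length(vocab$filler)),
                              function(m) (1 / seq_len(m)) / sum(1 / seq_len(m))),
                       use.names = FALSE)
  alpha0 <- log(2 * nF)  # filler baseline weight

  survey_days <- sort(unique(c(tps - 1L, tps)))
  words <- with_local_seed(cf$seed + 3L, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      extra <- sample(setdiff(seq_len(max(tps)), survey_days),
                      cf$extra_days)
      days <- sort(unique(c(survey_days, extra)))
      dl <- vector("list", length(days))
      for (k in seq_along(days)) {
        day <- days[k]
        # latent feature value on this day: the survey-occasion value on
        # adjacent days, fresh noise otherwise
        j <- match(TRUE, tps == day | tps == day + 1L)
        zd <- if (!is.na(j)) lat$z[i, j, ]
              else sd_b * lat$b_feat[i, ] + sd_w * stats::rnorm(nF)
        wcat <- c(exp(alpha0), exp(cf$softmax_beta * zd))
        catp <- wcat / sum(wcat)  # softmax over filler + categories
        p <- catp[word_cat + 1L] * wgt_within
        total <- stats::rpois(1, cf$words_per_day_mean)
        if (total == 0) { dl[[k]] <- NULL; next }
        cnt <- as.vector(stats::rmultinom(1, total, p))
        nz <- cnt > 0
        dl[[k]] <- data.frame(participant_id = ids[i],
                              date = origin + day,
                              word = all_words[nz], count = cnt[nz])
      }
      out[[i]] <- do.call(rbind, dl)
    }
    do.call(rbind, out)
  })

  ## Stream 4: missingness ----------------------------------------------------
  miss <- with_local_seed(cf$seed + 4L, {
    sv <- survey
    if (cf$missing_rate_survey > 0) {
      if (cf$missing_mode == "MCAR") {
        keep <- stats::runif(nrow(sv)) >= cf$missing_rate_survey
      } else {
        j <- match(sv$timepoint_day, tps)
        i <- match(sv$participant_id, ids)
        sev <- rowMeans(matrix(lat$eta[cbind(rep(i, nD), rep(j, nD),
                                             rep(seq_len(nD), each = nrow(sv)))],
                               nrow(sv), nD))
        pm <- stats::plogis(stats::qlogis(cf$missing_rate_survey) +
                              cf$mar_strength * sev)
        keep <- stats::runif(nrow(sv)) >= pm
      }
      sv <- sv[keep, , drop = FALSE]
    }
    wb <- words
    if (cf$missing_rate_words > 0 && !is.null(wb)) {
      daykey <- unique(wb[c("participant_id", "date")])
      drop <- stats::runif(nrow(daykey)) < cf$missing_rate_words
      bad <- daykey[drop, , drop = FALSE]
      if (nrow(bad)) {
        key <- paste(wb$participant_id, wb$date)
        wb <- wb[!(key %in% paste(bad$participant_id, bad$date)), , drop = FALSE]
      }
    }
    list(survey = sv, words = wb)
  })

  ## Stream 5: device log and completion rates -------------------------------
  side <- with_local_seed(cf$seed + 5L, {
    switchers <- stats::runif(n) < cf$os_switch_rate
    device_log <- data.frame(
      participant_id = rep(ids, each = 2),
      date = rep(origin + c(0, 90), n),
      os = as.vector(rbind("android", ifelse(switchers, "ios", "android"))))
    exp_items <- sum(vapply(cf$item_loadings, length, 0L)) * Tn
    obs_items <- table(factor(miss$survey$participant_id, levels = ids))
    exp_days <- length(survey_days) + cf$extra_days
    obs_days <- if (is.null(miss$words)) rep(0, n) else
      as.vector(table(factor(unique(miss$words[c("participant_id", "date")])$participant_id,
                             levels = ids)))
    completion <- data.frame(
      participant_id = rep(ids, 2),
      activity = rep(c("flash_survey", "word_collection"), each = n),
      completion_rate = c(as.vector(obs_items) / exp_items,
                          obs_days / exp_days))
    list(device_log = device_log, completion = completion)
  })

  schedule <- data.frame(
    participant_id = rep(ids, each = Tn),
    timepoint_day = rep(tps, n),
    date = rep(origin + tps, n))

  domain_spec <- lapply(seq_len(nD), function(d) {
    list(domain = sprintf("domain%02d", d),
         items = sprintf("d%02d_i%d", d, seq_along(cf$item_loadings[[d]])),
         timepoints = tps)
  })
  names(domain_spec) <- vapply(domain_spec, `[[`, "", "domain")

  sev_truth <- data.frame(
    participant_id = rep(rep(ids, Tn), nD),
    timepoint_day = rep(rep(tps, each = n), nD),
    domain = rep(sprintf("domain%02d", seq_len(nD)), each = n * Tn),
    eta = as.vector(lat$eta))
  feat_truth <- data.frame(
    participant_id = rep(rep(ids, Tn), nF),
    timepoint_day = rep(rep(tps, each = n), nF),
    feature = rep(names(cat_words), each = n * Tn),
    z = as.vector(lat$z))
  planted_df <- do.call(rbind, lapply(cf$planted_pairs, function(pp)
    data.frame(feature = names(cat_words)[pp$feature],
               domain = sprintf("domain%02d", pp$domain),
               rho_b = pp$rho_b, rho_w = pp$rho_w)))

  structure(list(
    word_bags = miss$words, survey_items = miss$survey,
    schedule = schedule, device_log = side$device_log,
    completion = side$completion, domain_spec = domain_spec,
    truth = structure(list(severity = sev_truth, features = feat_truth,
                           planted = planted_df), class = "cohort_truth"),
    config = cf
  ), class = "lm_cohort")
}

#' Write a simulated cohort to delimited-text fixture files
#'
#' Writes the analysis input tables as CSV, the domain spec as JSON, and the
#' ground truth as a clearly named `truth.json` sidecar that the pipeline
#' never reads. A round-trip through [read_word_bags()] /
#' [read_survey_items()] returns tables equal to the in-memory originals.
#'
#' @param cohort an `lm_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
write_fixture <- function(cohort, dir) {
  stopifnot(inherits(cohort, "lm_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(x) file.path(dir, x)
  wcsv <- function(df, path) utils::write.csv(df, path, row.names = FALSE)
  wcsv(cohort$word_bags, p("word_bags.csv"))
  wcsv(cohort$survey_items, p("survey_items.csv"))
  wcsv(cohort$schedule, p("schedule.csv"))
  wcsv(cohort$device_log, p("device_log.csv"))
  wcsv(cohort$completion, p("completion.csv"))
  jsonlite::write_json(cohort$domain_spec, p("domain_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(lapply(unclass(cohort$truth), identity), p("truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  c(word_bags = p("word_bags.csv"), survey_items = p("survey_items.csv"),
    schedule = p("schedule.csv"), device_log = p("device_log.csv"),
    completion = p("completion.csv"), domain_spec = p("domain_spec.json"),
    truth = p("truth.json"))
}

#' Read a word-bag table written by [write_fixture()]
#' @param path CSV with columns participant_id, date, word, count.
#' @return data frame with `date` parsed as `Date`.
#' @export
read_word_bags <- function(path) {
  df <- utils::read.csv(path, colClasses = c(participant_id = "character",
                                             date = "Date",
                                             word = "character",
                                             count = "integer"))
  df
}

#' Read a survey-item table written by [write_fixture()]
#' @param path CSV with columns participant_id, timepoint_day, item_id, value.
#' @return data frame; absent rows encode missing responses.
#' @export
read_survey_items <- function(path) {
  utils::read.csv(path, colClasses = c(participant_id = "character",
                                       timepoint_day = "integer",
                                       item_id = "character",
                                       value = "numeric"))
}
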