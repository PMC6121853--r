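#' Default ethogram
#'
#' Mapping of behavior codes to valence (aggressive, submissive, neutral)
#' used to score contest recordings. The default covers a typical cichlid
#' agonistic repertoire; supply your own two-column data frame
#' (`behavior_code`, `valence`) to override.
#'
#' @return data frame with columns `behavior_code` and `valence`.
#' @export
default_ethogram <- function() {
  data.frame(
    behavior_code = c("bite", "chase", "ram", "mouth_fight", "frontal_display",
                      "lateral_display", "flee", "submissive_posture",
                      "bitten", "hook", "swim", "hover", "dig"),
    valence = c(rep("aggressive", 6), rep("submissive", 4),
                rep("neutral", 3)),
    stringsAsFactors = FALSE)
}

#' Score an ethogram event stream
#'
#' Counts aggressive and submissive behavior events of one focal fish in a
#' time-sorted event stream; neutral events are ignored.
#'
#' @param events data frame with columns `time_s`, `actor_id`,
#'   `behavior_code`, sorted by time.
#' @param fish_id focal fish.
#' @param ethogram behavior-code to valence mapping (see [default_ethogram()]).
#' @return named integer vector `c(aggressive = ..., submissive = ...)`.
#' @export
score_ethogram <- function(events, fish_id, ethogram = default_ethogram()) {
  if (nrow(events) == 0)
    return(c(aggressive = 0L, submissive = 0L))
  if (is.unsorted(events$time_s))
    stop("events must be sorted by time_s", call. = FALSE)
  unknown <- setdiff(unique(events$behavior_code), ethogram$behavior_code)
  if (length(unknown))
    stop("behavior code(s) not in ethogram: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  ev <- events[events$actor_id == fish_id, ]
  val <- ethogram$valence[match(ev$behavior_code, ethogram$behavior_code)]
  c(aggressive = sum(val == "aggressive"),
    submissive = sum(val == "submissive"))
}

#' Fighting-ability index
#'
#' The difference between the number of aggressive and submissive behaviors
#' a fish performed during a contest. Positive values mark fish that mostly
#' attacked; negative values fish that mostly submitted.
#'
#' @param aggressive_count,submissive_count non-negative counts.
#' @return integer index (may be negative).
#' @export
fighting_ability <- function(aggressive_count, submissive_count) {
  if (any(aggressive_count < 0) || any(submissive_count < 0))
    stop("behavior counts must be non-negative", call. = FALSE)
  as.integer(aggressive_count) - as.integer(submissive_count)
}

check_dyads <- function(dyads) {
  need <- c("pair_id", "fish_id", "sex", "standard_length_cm", "mass_g",
            "stripe_begin", "stripe_end", "aggressive_count",
            "submissive_count", "winner")
  miss <- setdiff(need, names(dyads))
  if (length(miss))
    stop("dyad table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  sizes <- table(dyads$pair_id)
  if (any(sizes != 2))
    stop("every pair_id must appear exactly twice", call. = FALSE)
  wins <- tapply(dyads$winner, dyads$pair_id, sum)
  if (any(wins != 1))
    stop("each pair must have exactly one winner", call. = FALSE)
  invisible(dyads)
}

#' Dyad matching check
#'
#' Tests whether within-pair differences in standard length and body mass
#' are centred on zero, i.e. whether dyads were successfully size-matched.
#' Pairs are matched by design, so a paired Wilcoxon signed-rank procedure is
#' used (the conventional `V` statistic); exact p-values for n <= 25 pairs,
#' a normal approximation with continuity correction otherwise.
#'
#' @param dyads dyad table, one row per fish, with `pair_id`,
#'   `standard_length_cm`, `mass_g`.
#' @return data frame, one row per variable, with `variable`, `mean_diff`,
#'   `sd_diff`, `V`, `p`. All-zero differences report p = 1.
#' @export
matching_test <- function(dyads) {
  check_dyads(dyads)
  pairs <- split(dyads, dyads$pair_id)
  if (length(pairs) < 6) stop("need at least 6 pairs", call. = FALSE)
  one <- function(var) {
    # signed per-pair difference, first-listed fish minus second
    d <- vapply(pairs, function(p) p[[var]][1] - p[[var]][2], numeric(1))
    if (all(d == 0))
      return(data.frame(variable = var, mean_diff = 0, sd_diff = 0,
                        V = NA_real_, p = 1))
    wt <- suppressWarnings(
      stats::wilcox.test(d, exact = length(d) <= 25, correct = TRUE))
    data.frame(variable = var, mean_diff = mean(abs(d)),
               sd_diff = stats::sd(abs(d)), V = unname(wt$statistic),
               p = wt$p.value)
  }
  rbind(one("standard_length_cm"), one("mass_g"))
}

#' Contest outcome linear mixed model
#'
#' Tests whether body mass or fighting ability differ between winners and
#' losers, and between the sexes, via a random-intercept (pair) LMM with
#' combat success, sex and their interaction as fixed effects.
#'
#' @param dyads dyad table (one row per fish; see [matching_test()] for the
#'   required columns).
#' @param response `"mass"` or `"fighting_ability"`.
#' @return a [mixed_model_fit]; F-tests use containment denominator df.
#' @export
outcome_lmm <- function(dyads, response = c("mass", "fighting_ability")) {
  response <- match.arg(response)
  check_dyads(dyads)
  if (length(unique(dyads$pair_id)) < 6)
    stop("need at least 6 pairs", call. = FALSE)
  y <- if (response == "mass") dyads$mass_g
       else fighting_ability(dyads$aggressive_count, dyads$submissive_count)
  dat <- data.frame(y = as.numeric(y),
                    success = factor(ifelse(dyads$winner, "winner", "loser"),
                                     levels = c("loser", "winner")),
                    sex = factor(dyads$sex),
                    pair_id = factor(dyads$pair_id))
  dat <- use_sum_contrasts(dat)
  form <- y ~ success * sex + (1 | pair_id)
  if (nlevels(dat$sex) < 2) {
    warning("single sex present; dropping sex and interaction", call. = FALSE)
    form <- y ~ success + (1 | pair_id)
  }
  fit <- lme4::lmer(form, data = dat, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  at <- containment_anova(fit, dat$pair_id)
  sw <- stats::shapiro.test(stats::resid(fit))$p.value
  out <- new_mixed_model_fit(fit, at, shapiro_p = sw, response = response)
  out$data <- dat
  out$success_effect <- effect_of(out, "success", "winner", "loser")
  out
}

#' Stripe-state / contest-outcome association
#'
#' Binomial (logit) mixed model of combat success on horizontal-stripe state
#' at the chosen timepoint, with pair as random intercept; the stripe effect
#' is assessed by a single-df likelihood-ratio test. The end-of-contest
#' stripe state reflects current dominance; the begin state should not
#' predict the coming outcome.
#'
#' If the outcome is completely separated by stripe state (some stripe level
#' contains only winners or only losers), the mixed model likelihood is
#' degenerate: the fit is flagged and a bias-reduced (Firth) fixed-effects
#' logistic fit provides the reported odds ratio, with a warning.
#'
#' @param dyads dyad table.
#' @param timepoint `"end"` (default) or `"begin"`.
#' @return list of class `stripe_outcome_fit`: `chisq`, `df`, `p`,
#'   `odds_ratio` (odds of winning for dark vs pale stripe), `separation`
#'   flag, and the underlying `fit`.
#' @export
stripe_outcome_glmm <- function(dyads, timepoint = c("end", "begin")) {
  timepoint <- match.arg(timepoint)
  check_dyads(dyads)
  stripe <- if (timepoint == "end") dyads$stripe_end else dyads$stripe_begin
  dat <- data.frame(win = as.integer(dyads$winner),
                    stripe = factor(stripe, levels = c("pale", "dark")),
                    pair_id = factor(dyads$pair_id))
  if (nlevels(droplevels(dat$stripe)) < 2) {
    warning("stripe state is constant at this timepoint; no test possible",
            call. = FALSE)
    return(structure(list(chisq = 0, df = 1, p = 1, odds_ratio = NA_real_,
                          separation = FALSE, fit = NULL),
                     class = "stripe_outcome_fit"))
  }
  tab <- table(dat$stripe, dat$win)
  separation <- any(tab == 0)
  if (separation) {
    warning("complete separation of outcome by stripe state; ",
            "using bias-reduced logistic fit", call. = FALSE)
    X <- stats::model.matrix(~stripe, dat)
    fl <- firth_logistic(X, dat$win)
    # LRT from the unpenalized fixed-effects deviances (glm handles
    # separation with finite deviance even if estimates diverge)
    g1 <- suppressWarnings(stats::glm(win ~ stripe, binomial, dat))
    g0 <- stats::glm(win ~ 1, binomial, dat)
    chisq <- g0$deviance - g1$deviance
    return(structure(list(chisq = chisq, df = 1,
                          p = stats::pchisq(chisq, 1, lower.tail = FALSE),
                          odds_ratio = exp(unname(fl$coefficients[2])),
                          separation = TRUE, fit = fl),
                     class = "stripe_outcome_fit"))
  }
  fit1 <- suppressMessages(lme4::glmer(
    win ~ stripe + (1 | pair_id), data = dat, family = stats::binomial,
    control = lme4::glmerControl(check.conv.singular = "ignore")))
  fit0 <- suppressMessages(lme4::glmer(
    win ~ 1 + (1 | pair_id), data = dat, family = stats::binomial,
    control = lme4::glmerControl(check.conv.singular = "ignore")))
  lrt <- stats::anova(fit1, fit0)
  chisq <- lrt$Chisq[2]
  structure(list(chisq = chisq, df = lrt$Df[2],
                 p = lrt$`Pr(>Chisq)`[2],
                 odds_ratio = exp(unname(lme4::fixef(fit1)["stripedark"])),
                 separation = FALSE, fit = fit1),
            class = "stripe_outcome_fit")
}

#' @export
print.stripe_outcome_fit <- function(x, ...) {
  cat(sprintf("Stripe-state vs contest outcome (binomial GLMM LRT)\n"))
  cat(sprintf("  chi-squared(%d) = %.3f, p = %.4g\n", x$df, x$chisq, x$p))
  cat(sprintf("  odds ratio (win | dark vs pale stripe): %.3g\n",
              x$odds_ratio))
  if (x$separation)
    cat("  note: complete separation; bias-reduced logistic fallback used\n")
  invisible(x)
}
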