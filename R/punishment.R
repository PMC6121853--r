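#' Validate a mirror-image-stimulation trial table
#'
#' Each fish is tested twice, with two distinct treatments out of
#' darkened / paled / control, in randomized order. Latencies are censored
#' at the trial duration when no attack occurred.
#'
#' @param trials data frame with columns `fish_id`, `sex`, `treatment`
#'   (`darkened`, `paled`, `control`), `order_index` (1 or 2),
#'   `aggressive_bouts`, `latency_s`, `censored`.
#' @return `trials`, invisibly, after validation.
#' @export
validate_mis_trials <- function(trials) {
  need <- c("fish_id", "sex", "treatment", "order_index", "aggressive_bouts",
            "latency_s", "censored")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(trials$treatment %in% c("darkened", "paled", "control")))
    stop("treatment must be darkened, paled or control", call. = FALSE)
  per_fish <- split(trials$treatment, trials$fish_id)
  bad <- names(per_fish)[vapply(per_fish, function(t)
    length(t) != 2 || anyDuplicated(t) > 0, logical(1))]
  if (length(bad))
    stop("each fish needs exactly 2 trials with 2 distinct treatments; ",
         "offending fish: ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  if (any(trials$aggressive_bouts < 0) || any(trials$latency_s <= 0))
    stop("bouts must be >= 0 and latencies > 0", call. = FALSE)
  invisible(trials)
}

#' Mirror-trial linear mixed model
#'
#' LMM of the aggression received by manipulated signalers: response is
#' aggressive bouts (square-root transformed, which normalises the
#' overdispersed counts) or latency to attack (untransformed by default; a
#' log option is available). Fixed effects are treatment, sex and their
#' interaction; individual and treatment order enter as crossed random
#' intercepts since every fish is tested twice. Censored latencies (no
#' attack within the trial) are excluded from the latency model.
#'
#' @param trials validated MIS trial table.
#' @param response `"bouts"` or `"latency"`.
#' @param latency_transform `"identity"` (default) or `"log"`.
#' @return a [mixed_model_fit]; F-tests use containment denominator df with
#'   individual as the containment group.
#' @export
mis_lmm <- function(trials, response = c("bouts", "latency"),
                    latency_transform = c("identity", "log")) {
  response <- match.arg(response)
  latency_transform <- match.arg(latency_transform)
  validate_mis_trials(trials)
  if (length(unique(trials$fish_id)) < 10)
    stop("need at least 10 fish", call. = FALSE)
  missing_trt <- setdiff(c("darkened", "paled", "control"),
                         unique(trials$treatment))
  if (length(missing_trt))
    stop("treatment level(s) absent from the data: ",
         paste(missing_trt, collapse = ", "), call. = FALSE)
  d <- trials
  transform <- "identity"
  if (response == "bouts") {
    d$y <- sqrt(d$aggressive_bouts)
    transform <- "sqrt"
  } else {
    d <- d[!d$censored, ]
    d$y <- if (latency_transform == "log") log(d$latency_s) else d$latency_s
    transform <- latency_transform
  }
  dat <- data.frame(y = d$y,
                    treatment = factor(d$treatment,
                                       levels = c("control", "paled",
                                                  "darkened")),
                    sex = factor(d$sex),
                    fish_id = factor(d$fish_id),
                    order_index = factor(d$order_index))
  dat <- use_sum_contrasts(dat)
  fit <- lme4::lmer(y ~ treatment * sex + (1 | fish_id) + (1 | order_index),
                    data = dat, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  at <- containment_anova(fit, dat$fish_id)
  sw <- stats::shapiro.test(stats::resid(fit))$p.value
  out <- new_mixed_model_fit(fit, at, shapiro_p = sw,
                             response = paste("MIS", response),
                             transform = transform)
  out$data <- dat
  out
}

#' Tukey HSD post-hoc treatment contrasts
#'
#' All three pairwise treatment comparisons (darkened-control, paled-control,
#' darkened-paled) on the fixed effects of a [mis_lmm()] fit, with
#' single-step familywise adjustment (multivariate-normal reference) of the
#' z statistics.
#'
#' @param fit a [mixed_model_fit] from [mis_lmm()].
#' @return data frame: `comparison`, `estimate`, `se`, `z`, `p_adj`.
#' @export
tukey_posthoc <- function(fit) {
  stopifnot(inherits(fit, "mixed_model_fit"))
  # with sum-to-zero contrasts the treatment comparisons are main-effect
  # differences averaged over sex; mcp's interaction warning is expected
  gl <- suppressWarnings(
    multcomp::glht(fit$fit, linfct = multcomp::mcp(treatment = "Tukey")))
  s <- summary(gl, test = multcomp::adjusted("single-step"))
  data.frame(comparison = names(s$test$coefficients),
             estimate = unname(s$test$coefficients),
             se = unname(s$test$sigma),
             z = unname(s$test$tstat),
             p_adj = unname(s$test$pvalues),
             stringsAsFactors = FALSE)
}

#' Fold effects of signal manipulation
#'
#' Mean-ratio effect sizes on the raw scales: how many times more aggression
#' (bouts) darkened-stripe fish receive than paled and control fish, and how
#' many times shorter the latency to attack is for manipulated than control
#' fish. Censored latencies are excluded from latency means but counted.
#' Percentile bootstrap confidence intervals resample fish (both their
#' trials together).
#'
#' @param trials MIS trial table.
#' @param n_boot bootstrap resamples (default 2000).
#' @param conf confidence level (default 0.95).
#' @param seed optional integer seed for the bootstrap.
#' @return data frame: `effect`, `ratio`, `ci_lo`, `ci_hi`, plus attribute
#'   `n_censored`. Ratios with a zero denominator are reported as `NA`.
#' @export
fold_effects <- function(trials, n_boot = 2000, conf = 0.95, seed = NULL) {
  validate_mis_trials(trials)
  if (!is.null(seed)) set.seed(seed)
  ratios <- function(d) {
    mb <- tapply(d$aggressive_bouts, d$treatment, mean)
    dl <- d[!d$censored, ]
    ml <- tapply(dl$latency_s, dl$treatment, mean)
    safe <- function(num, den) if (is.na(den) || den == 0) NA_real_
                               else num / den
    c(bouts_darkened_vs_paled = safe(mb["darkened"], mb["paled"]),
      bouts_darkened_vs_control = safe(mb["darkened"], mb["control"]),
      bouts_paled_vs_control = safe(mb["paled"], mb["control"]),
      latency_control_vs_darkened = safe(ml["control"], ml["darkened"]),
      latency_control_vs_paled = safe(ml["control"], ml["paled"]))
  }
  est <- ratios(trials)
  fish <- unique(trials$fish_id)
  by_fish <- split(trials, trials$fish_id)
  boot <- replicate(n_boot, {
    res <- do.call(rbind, by_fish[sample(length(fish), replace = TRUE)])
    ratios(res)
  })
  a <- (1 - conf) / 2
  ci <- apply(boot, 1, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
  out <- data.frame(effect = sub("\\..*$", "", names(est)),
                    ratio = unname(est),
                    ci_lo = unname(ci[1, ]), ci_hi = unname(ci[2, ]),
                    stringsAsFactors = FALSE)
  out$effect <- c("bouts_darkened_vs_paled", "bouts_darkened_vs_control",
                  "bouts_paled_vs_control", "latency_control_vs_darkened",
                  "latency_control_vs_paled")
  attr(out, "n_censored") <- sum(trials$censored)
  out
}
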