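#' Facial color patch labels
#'
#' Canonical order of the five facial patches of the study species' mask:
#' two black melanic stripes (horizontal and vertical), white, blue and
#' yellow. Pair labels in contrast records follow this order.
#'
#' @return character vector of patch labels.
#' @export
patch_labels <- function() {
  c("black_horizontal_stripe", "black_vertical_stripe", "white", "blue",
    "yellow")
}

PATCH_STATES <- c("dominant", "subordinate", "manipulated_dark",
                  "manipulated_pale", "control")

#' Color patch
#'
#' One measured (or synthesised) reflectance spectrum of a facial patch of
#' one fish in one signalling state.
#'
#' @param fish_id fish label.
#' @param state one of `dominant`, `subordinate`, `manipulated_dark`,
#'   `manipulated_pale`, `control`.
#' @param patch_label patch name (see [patch_labels()]; extensible).
#' @param reflectance reflectance [spectrum].
#' @return object of class `color_patch`.
#' @export
color_patch <- function(fish_id, state, patch_label, reflectance) {
  if (!state %in% PATCH_STATES)
    stop("unknown state '", state, "'; expected one of: ",
         paste(PATCH_STATES, collapse = ", "), call. = FALSE)
  stopifnot(inherits(reflectance, "spectrum"))
  structure(list(fish_id = as.character(fish_id), state = state,
                 patch_label = as.character(patch_label),
                 reflectance = reflectance),
            class = "color_patch")
}

#' Patch adjacency map
#'
#' Symmetric, irreflexive relation over patch labels recording which patches
#' physically border each other in the color pattern. Conspicuous pattern
#' design predicts higher contrasts between adjacent than nonadjacent
#' elements.
#'
#' @param adjacent_pairs two-column character matrix or data frame of
#'   adjacent patch pairs.
#' @param labels all patch labels in the dataset.
#' @return object of class `adjacency_map`.
#' @export
adjacency_map <- function(adjacent_pairs, labels = patch_labels()) {
  ap <- as.matrix(adjacent_pairs)
  if (ncol(ap) != 2) stop("adjacent_pairs must have two columns", call. = FALSE)
  if (any(ap[, 1] == ap[, 2]))
    stop("adjacency is irreflexive: a patch cannot border itself", call. = FALSE)
  unknown <- setdiff(c(ap), labels)
  if (length(unknown))
    stop("adjacent pair mentions unknown patch(es): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  m <- matrix(FALSE, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (i in seq_len(nrow(ap))) {
    m[ap[i, 1], ap[i, 2]] <- TRUE
    m[ap[i, 2], ap[i, 1]] <- TRUE
  }
  structure(list(matrix = m, labels = labels), class = "adjacency_map")
}

#' @rdname adjacency_map
#' @details `default_adjacency()` encodes the five-patch facial mask
#'   qualitatively: the horizontal stripe borders white, blue and yellow; the
#'   vertical stripe borders white and blue; white additionally borders blue.
#'   All other pairs (notably the two black stripes, and yellow with white or
#'   blue) are nonadjacent. Override with a custom map when patch geometry is
#'   known.
#' @export
default_adjacency <- function() {
  adjacency_map(rbind(
    c("black_horizontal_stripe", "white"),
    c("black_horizontal_stripe", "blue"),
    c("black_horizontal_stripe", "yellow"),
    c("black_vertical_stripe", "white"),
    c("black_vertical_stripe", "blue"),
    c("white", "blue")))
}

#' @rdname adjacency_map
#' @param map an `adjacency_map`.
#' @param a,b patch labels.
#' @export
is_adjacent <- function(map, a, b) {
  stopifnot(inherits(map, "adjacency_map"))
  missing <- setdiff(c(a, b), map$labels)
  if (length(missing))
    stop("patch(es) missing from adjacency map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  map$matrix[cbind(a, b)]
}

order_pair <- function(a, b, labels) {
  ord <- match(c(a, b), labels)
  if (any(is.na(ord))) { # extensible labels: fall back to alphabetical
    if (a <= b) c(a, b) else c(b, a)
  } else if (ord[1] <= ord[2]) c(a, b) else c(b, a)
}

#' Pairwise patch contrasts
#'
#' Computes the receptor-noise-limited chromatic (Delta-S) and achromatic
#' (Delta-L) contrast for every unordered pair of patches of each fish/state,
#' as seen by `system` under the ambient light of `env` at depth.
#'
#' @param patches list of [color_patch] objects (>= 2 per fish/state).
#' @param adjacency an [adjacency_map] covering every patch label present.
#' @param system a [visual_system].
#' @param env a [light_environment].
#' @return data frame of contrast records: `fish_id`, `state`, `patch_a`,
#'   `patch_b` (ordered by the canonical label order), `adjacent`, `delta_S`,
#'   `delta_L` (both in JND).
#' @export
pairwise_contrasts <- function(patches, adjacency, system, env) {
  stopifnot(is.list(patches), inherits(adjacency, "adjacency_map"),
            inherits(system, "visual_system"),
            inherits(env, "light_environment"))
  illum <- ambient_irradiance(env)
  meta <- data.frame(
    fish_id = vapply(patches, `[[`, character(1), "fish_id"),
    state = vapply(patches, `[[`, character(1), "state"),
    patch_label = vapply(patches, `[[`, character(1), "patch_label"),
    stringsAsFactors = FALSE)
  lab_missing <- setdiff(unique(meta$patch_label), adjacency$labels)
  if (length(lab_missing))
    stop("patch(es) have no adjacency entry: ",
         paste(lab_missing, collapse = ", "), call. = FALSE)
  groups <- split(seq_along(patches), paste(meta$fish_id, meta$state, sep = "\r"))
  out <- lapply(groups, function(idx) {
    if (length(idx) < 2)
      stop("fish/state group with fewer than 2 patches", call. = FALSE)
    qc <- lapply(idx, function(i)
      adapt(patches[[i]]$reflectance, illum, system))
    labs <- meta$patch_label[idx]
    combs <- utils::combn(seq_along(idx), 2)
    recs <- lapply(seq_len(ncol(combs)), function(k) {
      i <- combs[1, k]; j <- combs[2, k]
      pp <- order_pair(labs[i], labs[j], adjacency$labels)
      data.frame(fish_id = meta$fish_id[idx[1]], state = meta$state[idx[1]],
                 patch_a = pp[1], patch_b = pp[2],
                 adjacent = unname(is_adjacent(adjacency, labs[i], labs[j])),
                 delta_S = unname(chromatic_contrast(qc[[i]], qc[[j]], system)),
                 delta_L = unname(achromatic_contrast(qc[[i]], qc[[j]], system)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, recs)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Average contrasts per fish
#'
#' Because several patch pairs are measured per fish and reused across
#' comparisons, all adjacent and all nonadjacent contrasts are averaged per
#' individual (and state) before model fitting.
#'
#' @param records contrast records from [pairwise_contrasts()].
#' @return data frame with one row per fish/state/adjacency class:
#'   `fish_id`, `state`, `adjacent`, `mean_delta_S`, `mean_delta_L`,
#'   `n_pairs`. Fish lacking one adjacency class are dropped with a warning.
#' @export
aggregate_per_fish <- function(records) {
  stopifnot(nrow(records) > 0)
  agg <- stats::aggregate(
    cbind(mean_delta_S = records$delta_S, mean_delta_L = records$delta_L),
    by = list(fish_id = records$fish_id, state = records$state,
              adjacent = records$adjacent),
    FUN = mean)
  np <- stats::aggregate(list(n_pairs = records$delta_S),
                         by = list(fish_id = records$fish_id,
                                   state = records$state,
                                   adjacent = records$adjacent),
                         FUN = length)
  agg <- merge(agg, np)
  counts <- table(paste(agg$fish_id, agg$state))
  incomplete <- names(counts)[counts < 2]
  if (length(incomplete)) {
    warning("excluding fish/state without both adjacency classes: ",
            paste(incomplete, collapse = ", "), call. = FALSE)
    agg <- agg[!paste(agg$fish_id, agg$state) %in% incomplete, ]
  }
  agg[order(agg$fish_id, agg$state, !agg$adjacent), ]
}

#' Adjacency linear mixed model
#'
#' Random-intercept (fish) linear mixed model of per-fish mean contrasts,
#' fitted by REML. With `design = "dominant_only"` the single predictor is
#' adjacency (the Stage-1 conspicuousness test on dominant fish). With
#' `design = "dominant_and_subordinate"` the predictors are adjacency, stripe
#' intensity (dark in dominants, pale in subordinates) and their interaction
#' (the Stage-2 test of how paling reshapes the pattern). Achromatic
#' contrasts are square-root transformed before fitting; residual normality
#' is checked by a Shapiro-Wilk test and reported alongside the fit.
#'
#' @param aggregated output of [aggregate_per_fish()].
#' @param response `"chromatic"` (Delta-S) or `"achromatic"` (Delta-L,
#'   sqrt-transformed).
#' @param design `"dominant_only"` or `"dominant_and_subordinate"`.
#' @return a [mixed_model_fit] with term F-tests (containment df) and, for
#'   the two-state design, a sequential variance partition.
#' @export
adjacency_lmm <- function(aggregated,
                          response = c("chromatic", "achromatic"),
                          design = c("dominant_only",
                                     "dominant_and_subordinate")) {
  response <- match.arg(response)
  design <- match.arg(design)
  d <- aggregated
  if (design == "dominant_only") d <- d[d$state == "dominant", ]
  if (length(unique(d$fish_id)) < 4)
    stop("need at least 4 fish to fit the adjacency model", call. = FALSE)
  y <- if (response == "chromatic") d$mean_delta_S else sqrt(d$mean_delta_L)
  dat <- data.frame(y = y,
                    adjacency = factor(ifelse(d$adjacent, "adjacent",
                                              "nonadjacent"),
                                       levels = c("nonadjacent", "adjacent")),
                    stripe = factor(ifelse(d$state == "dominant", "dark",
                                           "pale"),
                                    levels = c("dark", "pale")),
                    fish_id = factor(d$fish_id))
  dat <- use_sum_contrasts(dat)
  form <- if (design == "dominant_only") y ~ adjacency + (1 | fish_id)
          else y ~ adjacency * stripe + (1 | fish_id)
  fit <- tryCatch(
    lme4::lmer(form, data = dat, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) stop("adjacency model could not be estimated: ",
                             conditionMessage(e), call. = FALSE))
  at <- containment_anova(fit, dat$fish_id)
  vp <- if (design == "dominant_only")
    sequential_varpart(y ~ adjacency, dat)
  else sequential_varpart(y ~ adjacency * stripe, dat)
  sw <- stats::shapiro.test(stats::resid(fit))$p.value
  out <- new_mixed_model_fit(
    fit, at, varpart = vp, shapiro_p = sw,
    response = paste(response, "contrast"),
    transform = if (response == "achromatic") "sqrt" else "identity")
  out$data <- dat
  out$adjacency_effect <- effect_of(out, "adjacency", "adjacent",
                                    "nonadjacent")
  out
}

#' Variance explained per fixed term
#'
#' Sequential (type-I) sum-of-squares decomposition of the fixed-effect
#' design on the transformed response, expressed as percent of the total
#' response variance. Term order follows the model formula (adjacency, then
#' stripe intensity, then their interaction).
#'
#' @param fit a [mixed_model_fit] from [adjacency_lmm()] (or any fit created
#'   with a stored variance partition).
#' @return data frame with `term`, `percent`, and `total_explained` (the sum
#'   over fixed terms, repeated on each row).
#' @export
variance_partition <- function(fit) {
  stopifnot(inherits(fit, "mixed_model_fit"))
  if (is.null(fit$varpart))
    stop("this fit carries no variance partition", call. = FALSE)
  fit$varpart
}

#' Per-pair-type dominance change tests
#'
#' For each patch-pair type, a two-sided Mann-Whitney (rank-sum) test of
#' whether the chromatic and the achromatic contrast differ between dominant
#' and subordinate fish, with Benjamini-Hochberg false-discovery-rate
#' adjustment across the family of pair types within each contrast kind
#' (chromatic and achromatic families are adjusted separately, matching
#' per-panel significance flags).
#'
#' @param records contrast records from [pairwise_contrasts()] containing
#'   both `dominant` and `subordinate` states.
#' @param alpha flag threshold on the adjusted p-value (default 0.05).
#' @return data frame: `patch_a`, `patch_b`, `kind` (chromatic/achromatic),
#'   `statistic` (Mann-Whitney U of dominant vs subordinate), `p`, `p_adj`,
#'   `significant`. Pair types with fewer than 2 observations per state are
#'   skipped with a warning.
#' @export
per_patch_change_tests <- function(records, alpha = 0.05) {
  if (!all(c("dominant", "subordinate") %in% records$state))
    stop("records must contain both dominant and subordinate states",
         call. = FALSE)
  r <- records[records$state %in% c("dominant", "subordinate"), ]
  key <- paste(r$patch_a, r$patch_b, sep = "\r")
  rows <- list()
  for (pt in unique(key)) {
    sub <- r[key == pt, ]
    dom <- sub[sub$state == "dominant", ]
    subo <- sub[sub$state == "subordinate", ]
    if (nrow(dom) < 2 || nrow(subo) < 2) {
      warning("skipping pair type ", gsub("\r", "-", pt),
              ": fewer than 2 observations per state", call. = FALSE)
      next
    }
    for (kind in c("chromatic", "achromatic")) {
      v <- if (kind == "chromatic") "delta_S" else "delta_L"
      wt <- suppressWarnings(
        stats::wilcox.test(dom[[v]], subo[[v]], exact = NULL))
      rows[[length(rows) + 1]] <- data.frame(
        patch_a = dom$patch_a[1], patch_b = dom$patch_b[1], kind = kind,
        statistic = unname(wt$statistic), p = wt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$p_adj <- NA_real_
  for (kind in unique(tab$kind)) {
    i <- tab$kind == kind
    tab$p_adj[i] <- stats::p.adjust(tab$p[i], method = "BH")
  }
  tab$significant <- tab$p_adj < alpha
  tab[order(tab$kind, tab$patch_a, tab$patch_b), ]
}
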