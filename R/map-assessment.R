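#' Stratum weights from mapped class areas
#'
#' @param mapped_areas Named or unnamed nonnegative vector of mapped area per
#'   class (pixels or hectares); at least one positive.
#' @param class_id Class codes (default `0..K-1`).
#' @return Tibble with `class_id`, `mapped_area`, `weight`; weights sum to 1.
#' @export
strata_weights <- function(mapped_areas, class_id = seq_along(mapped_areas) - 1L) {
  if (any(mapped_areas < 0)) stop("areas must be nonnegative", call. = FALSE)
  total <- sum(mapped_areas)
  if (total <= 0) stop("all mapped areas are zero", call. = FALSE)
  tibble::tibble(
    class_id = as.integer(class_id),
    mapped_area = as.numeric(mapped_areas),
    weight = mapped_areas / total
  )
}

#' Allocate reference samples to strata
#'
#' Proportional allocation by stratum weight, rounded with the
#' largest-remainder rule, then raised to a per-stratum minimum; the total is
#' kept at `n_total` by trimming the largest strata.
#'
#' @param weights Stratum weights (sum 1) or a [strata_weights()] tibble.
#' @param n_total Total sample size.
#' @param n_min Minimum samples per stratum.
#' @return Integer vector of per-stratum counts summing to `n_total`.
#' @export
allocate_samples <- function(weights, n_total, n_min = 1L) {
  if (is.data.frame(weights)) weights <- weights$weight
  k <- length(weights)
  if (n_total < k * n_min) stop("n_total too small for the per-stratum minimum", call. = FALSE)
  raw <- weights * n_total
  counts <- floor(raw)
  rem <- n_total - sum(counts)
  if (rem > 0) {
    frac_order <- order(raw - counts, decreasing = TRUE)
    counts[frac_order[seq_len(rem)]] <- counts[frac_order[seq_len(rem)]] + 1
  }
  counts <- pmax(counts, n_min)
  while (sum(counts) > n_total) {
    i <- which.max(counts)
    if (counts[i] <= n_min) break
    counts[i] <- counts[i] - 1
  }
  as.integer(counts)
}

#' Stratified estimates of accuracy and class areas
#'
#' Good-practices stratified estimation for a categorical map assessed with
#' a stratified random reference sample. With stratum (map class) weights
#' `W_i` and sample counts `n_ij` (map class i, reference class j), the cell
#' area proportions are `p_ij = W_i * n_ij / n_i.`; the overall accuracy is
#' the trace of `p`; user's accuracy of class i is `p_ii / p_i.` and
#' producer's accuracy of class j is `p_jj / p_.j`. Adjusted (error-corrected)
#' class areas are `total_area * p_.j` with the stratified standard error of
#' the column total, and confidence intervals at the given `z`.
#'
#' @param samples Tibble/data frame with columns `map` and `reference`
#'   (class codes `0..K-1`), one row per reference sample.
#' @param strata A [strata_weights()] tibble (every class with positive
#'   weight must appear among `samples$map`).
#' @param total_area Total mapped area in the output area unit (default: sum
#'   of `strata$mapped_area`).
#' @param z Normal quantile for confidence intervals (default 1.96).
#' @return A `lufor_strat_est` list: `p_hat` (K x K area-proportion matrix),
#'   `counts`, `overall` (+ SE), `by_class` tibble (users, producers,
#'   adjusted area, SEs, CIs), `total_area`, `z`.
#' @export
stratified_estimates <- function(samples, strata, total_area = sum(strata$mapped_area),
                                 z = 1.96) {
  # reference classes that were never mapped still need columns (and
  # zero-weight rows) so that no sample is dropped from the margins
  extra <- setdiff(unique(samples$reference), strata$class_id)
  if (length(extra) > 0) {
    strata <- dplyr::bind_rows(
      strata,
      tibble::tibble(class_id = as.integer(sort(extra)), mapped_area = 0, weight = 0)
    )
    strata <- strata[order(strata$class_id), ]
  }
  k <- nrow(strata)
  ids <- strata$class_id
  W <- strata$weight
  n <- matrix(0, k, k, dimnames = list(map = ids, reference = ids))
  tab <- table(factor(samples$map, levels = ids), factor(samples$reference, levels = ids))
  n[] <- as.numeric(tab)
  ni <- rowSums(n)
  if (any(W > 0 & ni == 0)) stop("a stratum with positive weight has no samples", call. = FALSE)

  prop <- n / ifelse(ni > 0, ni, 1) # n_ij / n_i.
  p_hat <- W * prop                 # rows scaled by weights
  overall <- sum(diag(p_hat))
  users <- ifelse(rowSums(p_hat) > 0, diag(p_hat) / rowSums(p_hat), 0)
  pj <- colSums(p_hat)
  producers <- ifelse(pj > 0, diag(p_hat) / pj, 0)

  # standard errors (stratified estimator for proportions)
  vterm <- W^2 * prop * (1 - prop) / pmax(ni - 1, 1) # per-cell variance terms
  vterm[ni <= 1, ] <- 0
  se_area_prop <- sqrt(colSums(vterm))
  se_overall <- sqrt(sum(W^2 * users * (1 - users) / pmax(ni - 1, 1) * (ni > 1)))
  se_users <- sqrt(users * (1 - users) / pmax(ni - 1, 1)) * (ni > 1)

  # producer's accuracy SE (error-adjusted totals in area units)
  Ni <- strata$mapped_area
  Nj_hat <- colSums(Ni * prop)
  se_producers <- numeric(k)
  for (j in seq_len(k)) {
    if (Nj_hat[j] <= 0) next
    others <- setdiff(seq_len(k), j)
    t1 <- if (ni[j] > 1) {
      Ni[j]^2 * (1 - producers[j])^2 * users[j] * (1 - users[j]) / (ni[j] - 1)
    } else 0
    t2 <- producers[j]^2 * sum(
      Ni[others]^2 * prop[others, j] * (1 - prop[others, j]) /
        pmax(ni[others] - 1, 1) * (ni[others] > 1)
    )
    se_producers[j] <- sqrt(t1 + t2) / Nj_hat[j]
  }

  by_class <- tibble::tibble(
    class_id = ids,
    weight = W,
    n_samples = as.integer(ni),
    users = unname(users), se_users = unname(se_users),
    producers = unname(producers), se_producers = se_producers,
    area_proportion = unname(pj), se_area_proportion = unname(se_area_prop),
    adjusted_area = unname(pj * total_area),
    se_adjusted_area = unname(se_area_prop * total_area),
    ci_lower = unname((pj - z * se_area_prop) * total_area),
    ci_upper = unname((pj + z * se_area_prop) * total_area)
  )
  structure(list(
    p_hat = p_hat, counts = n, overall = overall, se_overall = se_overall,
    by_class = by_class, total_area = total_area, z = z
  ), class = "lufor_strat_est")
}

#' @export
print.lufor_strat_est <- function(x, ...) {
  cat(sprintf("<lufor_strat_est> overall accuracy %.4f (SE %.4f), %d strata\n",
              x$overall, x$se_overall, nrow(x$by_class)))
  invisible(x)
}

#' @export
tidy.lufor_strat_est <- function(x, ...) {
  x$by_class
}

#' @export
glance.lufor_strat_est <- function(x, ...) {
  tibble::tibble(
    overall_accuracy = x$overall,
    se_overall = x$se_overall,
    total_area = x$total_area,
    n_samples = sum(x$counts),
    n_strata = nrow(x$by_class)
  )
}

#' Lustrum index of a loss year
#'
#' Bins 2001--2005, 2006--2010, 2011--2015, 2016--2020 map to 1..4.
#'
#' @param year Integer vector of loss years; 0 (no loss) maps to NA.
#' @return Integer lustrum indices.
#' @export
lustrum_of <- function(year) {
  out <- ifelse(year >= 2001 & year <= 2020, (year - 2001) %/% 5 + 1, NA_integer_)
  as.integer(out)
}

#' Lustrum labels
#' @export
lustrum_labels <- function() {
  c("2001-2005", "2006-2010", "2011-2015", "2016-2020")
}

#' Per-lustrum stratified assessment of a land-use map
#'
#' Pixels are binned by their forest-loss year into the four lustra; within
#' each bin stratum weights come from the mapped class areas, samples are
#' allocated proportionally (with a per-stratum minimum) and drawn at random
#' from the bin, reference labels are read from the reference map (an
#' optional interpreter error rate replaces a fraction of reference labels
#' with a random other class), and the stratified estimators are computed
#' independently per bin. Empty bins are reported and skipped.
#'
#' @param class_map Predicted H x W class map (codes `0..K-1`; other codes
#'   such as a no-data value are excluded).
#' @param loss_year H x W integer matrix (0 = no loss).
#' @param reference H x W reference class map (the generator's truth for
#'   synthetic assessments).
#' @param n_classes K.
#' @param n_total Reference samples per lustrum.
#' @param n_min Minimum samples per sampled stratum.
#' @param interpreter_error Probability a reference label is replaced by a
#'   random other class (default 0, a perfect interpreter).
#' @param pixel_area Area of one pixel in the output unit (e.g. ha).
#' @param z Confidence multiplier.
#' @param seed Sampling seed.
#' @return A tibble-indexed list of class `lufor_lustrum_assessment`:
#'   `estimates` (named list of `lufor_strat_est`, one per non-empty
#'   lustrum), `summary` tibble, `empty` labels of skipped bins.
#' @export
per_lustrum_assessment <- function(class_map, loss_year, reference, n_classes,
                                   n_total = 200L, n_min = 5L,
                                   interpreter_error = 0, pixel_area = 1,
                                   z = 1.96, seed = 1L) {
  stopifnot(all(dim(class_map) == dim(loss_year)), all(dim(class_map) == dim(reference)))
  yrs <- loss_year[loss_year > 0]
  if (length(yrs) > 0 && (min(yrs) < 2001 || max(yrs) > 2020)) {
    stop("loss years outside 2001-2020", call. = FALSE)
  }
  lus <- lustrum_of(loss_year)
  estimates <- list()
  empty <- character()
  rows <- list()
  withr::with_seed(seed, {
    for (b in 1:4) {
      label <- lustrum_labels()[b]
      in_bin <- which(!is.na(lus) & lus == b & class_map >= 0 & class_map < n_classes)
      if (length(in_bin) == 0) {
        empty <- c(empty, label)
        next
      }
      mapped <- class_map[in_bin]
      areas <- tabulate(mapped + 1L, nbins = n_classes) * pixel_area
      present <- which(areas > 0) - 1L
      strata <- strata_weights(areas[present + 1L], class_id = present)
      n_bin <- min(n_total, length(in_bin))
      n_min_b <- min(n_min, floor(n_bin / nrow(strata)))
      counts <- allocate_samples(strata, n_bin, n_min = max(1L, n_min_b))
      samp_idx <- integer(0)
      for (s in seq_len(nrow(strata))) {
        pool <- in_bin[mapped == strata$class_id[s]]
        take <- min(counts[s], length(pool))
        samp_idx <- c(samp_idx, if (length(pool) == 1) pool else sample(pool, take))
      }
      ref <- reference[samp_idx]
      if (interpreter_error > 0) {
        flip <- runif(length(ref)) < interpreter_error
        ref[flip] <- (ref[flip] + sample(n_classes - 1, sum(flip), replace = TRUE)) %% n_classes
      }
      samples <- tibble::tibble(map = class_map[samp_idx], reference = ref)
      est <- stratified_estimates(samples, strata, total_area = sum(areas), z = z)
      estimates[[label]] <- est
      rows[[label]] <- tibble::tibble(
        lustrum = label,
        n_pixels = length(in_bin),
        n_samples = sum(est$counts),
        overall_accuracy = est$overall,
        se_overall = est$se_overall
      )
    }
  })
  structure(list(
    estimates = estimates,
    summary = dplyr::bind_rows(rows),
    empty = empty
  ), class = "lufor_lustrum_assessment")
}

#' @export
print.lufor_lustrum_assessment <- function(x, ...) {
  cat("<lufor_lustrum_assessment>\n")
  print(x$summary)
  if (length(x$empty) > 0) cat("empty lustra:", paste(x$empty, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.lufor_lustrum_assessment <- function(x, ...) {
  purrr::imap_dfr(x$estimates, function(est, label) {
    out <- tidy(est)
    out$lustrum <- label
    out
  })
}
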