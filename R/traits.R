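#' Average daily gain from weekly body weights
#'
#' ADG is the within-animal ordinary least-squares regression slope of body
#' weight on age, in g/day.
#'
#' @param age_days numeric vector of ages (days)
#' @param bw_g numeric vector of body weights (g), same length
#' @return slope in g/day
#' @export
adg <- function(age_days, bw_g) {
  ok <- stats::complete.cases(age_days, bw_g)
  x <- age_days[ok]; y <- bw_g[ok]
  if (length(x) < 2L || length(unique(x)) < 2L)
    stop("ADG undefined: need >= 2 body weights at distinct ages")
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Cage average daily feed intake
#'
#' Total cage feed intake over the fattening period divided by the number of
#' days and the number of animals present.  Deaths are prorated through
#' animal-days: the effective animal count is `animal_days / days`.
#'
#' @param total_feed_g total feed delivered to the cage (g)
#' @param days length of the recording period (days)
#' @param animal_days sum over animals of days present (defaults to
#'   `n_animals * days` when `n_animals` is given instead)
#' @param n_animals optional constant occupancy shortcut
#' @return ADFI in g/day per animal
#' @export
adfi <- function(total_feed_g, days, animal_days = NULL, n_animals = NULL) {
  if (is.null(animal_days)) {
    if (is.null(n_animals)) stop("give animal_days or n_animals")
    animal_days <- n_animals * days
  }
  if (days <= 0 || animal_days <= 0)
    stop("ADFI undefined: zero denominator")
  total_feed_g / animal_days        # = total / (days * effective animals)
}

#' Feed conversion ratio
#'
#' Cage ADFI divided by cage-mean ADG: grams of feed per gram of gain.
#'
#' @param adfi_g_day cage ADFI (g/day)
#' @param cage_mean_adg_g_day cage-mean ADG (g/day), must be > 0
#' @return FCR (dimensionless ratio)
#' @export
fcr <- function(adfi_g_day, cage_mean_adg_g_day) {
  if (any(cage_mean_adg_g_day <= 0))
    stop("FCR undefined for non-positive cage-mean ADG")
  adfi_g_day / cage_mean_adg_g_day
}

#' Metabolic weight
#'
#' Body weight in kg raised to the metabolic exponent (default 3/4), a proxy
#' for maintenance requirement, evaluated at the body weight interpolated on
#' the mid-fattening day.
#'
#' @param bw_g body weight in grams, > 0
#' @param exponent metabolic exponent (default 0.75)
#' @return metabolic weight in kg^exponent
#' @export
metabolic_weight <- function(bw_g, exponent = 0.75) {
  if (any(bw_g <= 0)) stop("metabolic weight undefined for BW <= 0")
  (bw_g / 1000)^exponent
}

#' Residual feed intake across cages
#'
#' RFI is the residual of a batch-nested multiple regression of cage ADFI on
#' the cage-mean ADG and the cage-mean metabolic weight at mid-fattening:
#' feed eaten beyond the production + maintenance expectation.  By default
#' both the intercept and the two slopes are batch-specific ("nested");
#' `slopes = "common"` keeps batch intercepts but pools the slopes.
#'
#' @param cage_adfi numeric vector of cage ADFI (g/day)
#' @param cage_mean_adg numeric vector of cage-mean ADG (g/day)
#' @param cage_mean_mw numeric vector of cage-mean metabolic weight
#' @param batch factor (or coercible) of batch labels, one per cage
#' @param slopes `"nested"` (default) or `"common"`
#' @return residuals in cage order (g/day); within-batch mean is exactly 0
#'   under `"nested"`
#' @export
rfi <- function(cage_adfi, cage_mean_adg, cage_mean_mw, batch,
                slopes = c("nested", "common")) {
  slopes <- match.arg(slopes)
  batch <- factor(batch)
  n <- length(cage_adfi)
  stopifnot(length(cage_mean_adg) == n, length(cage_mean_mw) == n,
            length(batch) == n)
  if (slopes == "nested") {
    cnt <- table(batch)
    if (any(cnt < 4L))
      stop("batch ", names(cnt)[which(cnt < 4L)[1L]],
           " has fewer than 4 cages; nested RFI regression is undetermined")
    res <- numeric(n)
    for (b in levels(batch)) {
      k <- which(batch == b)
      X <- cbind(1, cage_mean_adg[k], cage_mean_mw[k])
      qr_x <- qr(X)
      if (qr_x$rank < ncol(X))
        stop("rank-deficient RFI regression within batch ", b)
      res[k] <- stats::lm.fit(X, cage_adfi[k])$residuals
    }
    res
  } else {
    X <- stats::model.matrix(~ batch + cage_mean_adg + cage_mean_mw)
    stats::lm.fit(X, cage_adfi)$residuals
  }
}

#' Weekly feed allowance under restricted feeding
#'
#' The restriction rule targets 75% of the expected ad-libitum intake: the
#' per-animal allowance for week *i* is `0.75 * (1 + 0.1)` times the observed
#' per-animal ad-libitum intake of the previous week (the 10% inflation
#' anticipates intake growth as animals grow), multiplied by the number of
#' animals present in the cage.
#'
#' @param prev_week_adlib_fi_per_animal previous-week ad-libitum feed intake,
#'   g/day per animal
#' @param n_animals animals present in the cage
#' @param restriction restriction target (default 0.75)
#' @param growth_allowance expected weekly intake growth (default 0.10)
#' @return cage allowance in g/day
#' @export
restricted_ration <- function(prev_week_adlib_fi_per_animal, n_animals,
                              restriction = 0.75, growth_allowance = 0.10) {
  if (any(prev_week_adlib_fi_per_animal < 0) || any(n_animals <= 0))
    stop("inputs must be positive")
  restriction * (1 + growth_allowance) *
    prev_week_adlib_fi_per_animal * n_animals
}

#' Derive individual and cage phenotypes from raw weekly records
#'
#' Runs the whole trait-derivation stage: per-animal ADG from the body-weight
#' trajectory, then for ad-libitum cages ADFI, FCR and RFI.  Input records
#' are assumed already trimmed to the controlled growing period (the final
#' medicated-feed week removed upstream).
#'
#' @param animals data frame: `animal, batch, parity, litter_size_class,
#'   size_class, cage, litter, regime` (regime `"F"` ad libitum, `"R"`
#'   restricted)
#' @param bw long data frame: `animal, age_days, bw_g`
#' @param cage_feed data frame: `cage, week, feed_g, animal_days`
#' @param days_per_week days covered by one feed record (default 7)
#' @param config a [default_config()] list (metabolic exponent, mid-fattening
#'   day, RFI slope variant)
#' @return list with
#'   \describe{
#'     \item{individual}{`animals` plus an `adg` column (g/day)}
#'     \item{cage}{per ad-libitum cage: `cage, batch, size_class, n_members,
#'       member list, adfi, mean_adg, mean_mw, fcr, rfi`}
#'   }
#' @export
derive_traits <- function(animals, bw, cage_feed, days_per_week = 7,
                          config = default_config()) {
  animals <- as.data.frame(animals)
  stopifnot(all(c("animal", "batch", "cage", "litter", "regime")
                %in% names(animals)))
  bw <- as.data.frame(bw)
  animals$animal <- as.character(animals$animal)
  bw$animal <- as.character(bw$animal)
  bw_split <- split(bw[, c("age_days", "bw_g")], bw$animal)
  adg_v <- rep(NA_real_, nrow(animals))
  mw_v <- rep(NA_real_, nrow(animals))
  for (i in seq_len(nrow(animals))) {
    rec <- bw_split[[animals$animal[i]]]
    if (is.null(rec) || sum(stats::complete.cases(rec)) < 2L) next
    adg_v[i] <- adg(rec$age_days, rec$bw_g)
    # BW interpolated at the mid-fattening day from the individual OLS line
    fit <- stats::lm.fit(cbind(1, rec$age_days), rec$bw_g)
    bw_mid <- fit$coefficients[1L] + fit$coefficients[2L] *
      config$mid_fattening_day
    mw_v[i] <- metabolic_weight(max(bw_mid, 1), config$metabolic_exponent)
  }
  animals$adg <- adg_v
  animals$mw_mid <- mw_v

  # cage-level traits for ad-libitum cages with feed records
  f_animals <- animals[animals$regime == "F", , drop = FALSE]
  cage_df <- NULL
  if (!is.null(cage_feed) && nrow(cage_feed) > 0L) {
    cage_feed <- as.data.frame(cage_feed)
    agg <- do.call(rbind, lapply(split(cage_feed, cage_feed$cage), function(d)
      data.frame(cage = d$cage[1L], feed_g = sum(d$feed_g),
                 days = days_per_week * nrow(d),
                 animal_days = sum(d$animal_days))))
    keep <- agg$cage %in% f_animals$cage
    agg <- agg[keep, , drop = FALSE]
    mem <- split(f_animals, f_animals$cage)
    rows <- lapply(seq_len(nrow(agg)), function(i) {
      m <- mem[[as.character(agg$cage[i])]]
      use <- !is.na(m$adg)            # members contributing >= 2 BW records
      data.frame(cage = agg$cage[i], batch = m$batch[1L],
                 size_class = if ("size_class" %in% names(m))
                   m$size_class[1L] else NA,
                 n_members = nrow(m),
                 members = I(list(m$animal)),
                 adfi = adfi(agg$feed_g[i], agg$days[i],
                             animal_days = agg$animal_days[i]),
                 mean_adg = mean(m$adg[use]),
                 mean_mw = mean(m$mw_mid[use]),
                 stringsAsFactors = FALSE)
    })
    cage_df <- do.call(rbind, rows)
    cage_df$fcr <- fcr(cage_df$adfi, cage_df$mean_adg)
    cage_df$rfi <- rfi(cage_df$adfi, cage_df$mean_adg, cage_df$mean_mw,
                       cage_df$batch, slopes = config$rfi_slopes)
  }
  list(individual = animals, cage = cage_df)
}
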