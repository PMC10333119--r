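# Taxonomic-neglect metrics: the neglect index (NI), its body-size and
# diversity drivers, per-decade description activity, author-dedication
# scores, and the corrected global species-richness extrapolation.

DECADES_DEFAULT <- c("1980-1989", "1990-1999", "2000-2009", "2010-2019")

#' Neglect index
#'
#' `NI = N_mOTU / N_sp`: the number of mOTUs detected for a family across
#' the whole dataset over the number of species ever described for it.
#' NI = 1 means the survey detected as many mOTUs as have been formally
#' described worldwide; a small NI means only a tiny share of described
#' diversity was sampled, and NI > 1 flags a dark taxon.
#'
#' @param n_motu mOTUs detected (>= 0).
#' @param n_sp described species (> 0).
#' @return the ratio (vectorised).
#' @export
neglect_index <- function(n_motu, n_sp) {
  stopifnot(all(n_motu >= 0))
  if (any(n_sp <= 0)) {
    stop("NI undefined: N_sp must be positive")
  }
  n_motu / n_sp
}

#' Mean-of-logs body size from a size range
#'
#' @param min_mm,max_mm body-size range limits in mm, `min_mm <= max_mm`.
#' @return `(ln(min) + ln(max)) / 2`.
#' @export
mean_log_body <- function(min_mm, max_mm) {
  stopifnot(all(min_mm > 0), all(min_mm <= max_mm))
  (log(min_mm) + log(max_mm)) / 2
}

#' Model the drivers of taxonomic neglect
#'
#' Fits `ln(NI) ~ ln(N_mOTU) * mean_log_body` first; if the interaction is
#' not significant at `alpha` it is removed and the additive model
#' `ln(NI) ~ ln(N_mOTU) + mean_log_body` is reported as final. Both fits
#' and the screening decision are returned.
#'
#' @param dossiers data.frame with `family`, `n_motu`, `n_sp`, and either
#'   `mean_log_body` or (`body_min_mm`, `body_max_mm`).
#' @param alpha significance level for the interaction screen (default
#'   0.05).
#' @return list with `final` (coefficient table: estimate, SE, t, p),
#'   `interaction_p`, `interaction_kept`, `fit_full`, `fit_additive`.
#' @export
fit_neglect_drivers <- function(dossiers, alpha = 0.05) {
  stopifnot(all(c("family", "n_motu", "n_sp") %in% names(dossiers)))
  if (!"mean_log_body" %in% names(dossiers)) {
    dossiers$mean_log_body <- mean_log_body(dossiers$body_min_mm,
                                            dossiers$body_max_mm)
  }
  ok <- dossiers$n_motu > 0 & dossiers$n_sp > 0
  d <- dossiers[ok, , drop = FALSE]
  if (nrow(d) < 4L) stop("need >= 4 dossiers with positive NI")
  d$log_ni <- log(neglect_index(d$n_motu, d$n_sp))
  d$log_motu <- log(d$n_motu)
  if (var(d$log_motu) == 0 || var(d$mean_log_body) == 0 ||
      abs(cor(d$log_motu, d$mean_log_body)) > 1 - 1e-10) {
    if (var(d$mean_log_body) == 0) {
      # degenerate predictor: body size constant, drop it
      fit <- lm(log_ni ~ log_motu, data = d)
      tab <- summary(fit)$coefficients
      return(list(final = tab, interaction_p = NA_real_,
                  interaction_kept = FALSE, fit_full = NULL,
                  fit_additive = fit))
    }
    stop("collinear predictors: ln(N_mOTU) and mean_log_body")
  }
  fit_full <- lm(log_ni ~ log_motu * mean_log_body, data = d)
  p_int <- summary(fit_full)$coefficients["log_motu:mean_log_body",
                                          "Pr(>|t|)"]
  fit_add <- lm(log_ni ~ log_motu + mean_log_body, data = d)
  keep <- is.finite(p_int) && p_int < alpha
  list(final = summary(if (keep) fit_full else fit_add)$coefficients,
       interaction_p = p_int,
       interaction_kept = keep,
       fit_full = fit_full,
       fit_additive = fit_add)
}

#' Assign years to decade bins
#'
#' @param year integer years.
#' @param decades decade labels of the form `"1980-1989"`.
#' @return character decade label, `NA` for out-of-range years.
#' @export
year_to_decade <- function(year, decades = DECADES_DEFAULT) {
  out <- rep(NA_character_, length(year))
  for (d in decades) {
    b <- decade_bounds(d)
    out[year >= b[1] & year <= b[2]] <- d
  }
  out
}

#' Species described per family per decade
#'
#' Counts described species (one record per species) per family per decade
#' over 1980-2019. Records outside the decade range are excluded and
#' logged.
#'
#' @param records description records with `species`, `family`, `year`.
#' @param decades decade labels.
#' @return list with `table` (family x decade integer matrix, `N_sp10`)
#'   and `excluded` (data.frame of out-of-range records).
#' @export
descriptions_per_decade <- function(records, decades = DECADES_DEFAULT) {
  stopifnot(all(c("species", "family", "year") %in% names(records)))
  dec <- year_to_decade(records$year, decades)
  excluded <- records[is.na(dec), , drop = FALSE]
  kept <- records[!is.na(dec), , drop = FALSE]
  dec <- dec[!is.na(dec)]
  fams <- sort(unique(records$family))
  tab <- matrix(0L, length(fams), length(decades),
                dimnames = list(fams, decades))
  if (nrow(kept)) {
    cnt <- table(kept$family, factor(dec, levels = decades))
    tab[rownames(cnt), ] <- as.integer(cnt)
  }
  list(table = tab, excluded = excluded)
}

#' Correlation between neglect and description activity
#'
#' Pearson correlation between `log(NI)` and `log(N_sp10 + offset)` over
#' family x decade pairs pooled across decades.
#'
#' @param nsp10 family x decade matrix from [descriptions_per_decade()].
#' @param ni named vector of NI values per family (names matching the
#'   matrix rows).
#' @param offset added to zero `N_sp10` cells before the log (default 1).
#' @return list `r`, `n`, `p_value`.
#' @export
neglect_activity_correlation <- function(nsp10, ni, offset = 1) {
  idx <- match(rownames(nsp10), names(ni))
  if (anyNA(idx)) {
    stop("families without NI: ",
         paste(rownames(nsp10)[is.na(idx)], collapse = ", "))
  }
  x <- rep(log(unname(ni[idx])), times = ncol(nsp10))
  counts <- as.vector(nsp10)
  y <- log(ifelse(counts == 0, counts + offset, counts))
  if (length(x) < 3) stop("need >= 3 pairs")
  if (var(x) == 0 || var(y) == 0) stop("zero variance")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), n = length(x), p_value = ct$p.value)
}

#' Test whether the neglect-activity slope changes across decades
#'
#' Nested-model ANOVA comparing `log(N_sp10) ~ log(NI)` against
#' `log(N_sp10) ~ log(NI) * Decade`: a significant F indicates that the
#' relation between description activity and neglect differs by decade.
#'
#' @inheritParams neglect_activity_correlation
#' @param decades decade labels expected in the data; all must be present.
#' @return list `f`, `df` (length-2), `p_value`, `anova`.
#' @export
decade_interaction_test <- function(nsp10, ni, offset = 1,
                                    decades = DECADES_DEFAULT) {
  missing <- setdiff(decades, colnames(nsp10))
  if (length(missing)) {
    stop("decades absent from table: ", paste(missing, collapse = ", "))
  }
  if (ncol(nsp10) < 2L) stop("need >= 2 decades for an interaction")
  idx <- match(rownames(nsp10), names(ni))
  if (anyNA(idx)) {
    stop("families without NI: ",
         paste(rownames(nsp10)[is.na(idx)], collapse = ", "))
  }
  counts <- as.vector(nsp10)
  dat <- data.frame(
    log_nsp10 = log(ifelse(counts == 0, counts + offset, counts)),
    log_ni = rep(log(unname(ni[idx])), times = ncol(nsp10)),
    decade = factor(rep(colnames(nsp10), each = nrow(nsp10)),
                    levels = colnames(nsp10)))
  m1 <- lm(log_nsp10 ~ log_ni, data = dat)
  m2 <- lm(log_nsp10 ~ log_ni * decade, data = dat)
  a <- anova(m1, m2)
  list(f = a$F[2L], df = c(a$Df[2L], a$Res.Df[2L]),
       p_value = a$`Pr(>F)`[2L], anova = a)
}

#' Per-author fractional description credit
#'
#' Each species described in study `j` contributes `1 / N_auth_j` to every
#' author of `j`; scores are summed per author (within a decade when
#' `decade` is given). Total credit equals the total number of species
#' described — credit is conserved.
#'
#' @param records description records with `species`, `year`, `authors`
#'   (semicolon-separated, non-empty).
#' @param decade restrict to one decade label, or `NULL` for all records.
#' @param decades decade labels used for binning.
#' @return data.frame `author`, `decade`, `score`, sorted by decreasing
#'   score.
#' @export
author_scores <- function(records, decade = NULL,
                          decades = DECADES_DEFAULT) {
  stopifnot(all(c("species", "year", "authors") %in% names(records)))
  if (any(is.na(records$authors) | records$authors == "")) {
    stop("records with empty author list")
  }
  dec <- year_to_decade(records$year, decades)
  if (!is.null(decade)) {
    keep <- !is.na(dec) & dec == decade
    records <- records[keep, , drop = FALSE]
    dec <- dec[keep]
  }
  auth_lists <- strsplit(records$authors, ";", fixed = TRUE)
  n_auth <- lengths(auth_lists)
  long <- data.frame(author = unlist(auth_lists),
                     decade = rep(dec, n_auth),
                     credit = rep(1 / n_auth, n_auth),
                     stringsAsFactors = FALSE)
  agg <- stats::aggregate(credit ~ author + decade, data = long, FUN = sum)
  names(agg)[names(agg) == "credit"] <- "score"
  agg[order(-agg$score, agg$author), c("author", "decade", "score")]
}

#' Count highly dedicated authors per decade
#'
#' Authors whose decade score strictly exceeds `s_threshold`.
#'
#' @param scores data.frame from [author_scores()].
#' @param s_threshold credit threshold (default 50).
#' @param decades decade labels to report (zero counts included).
#' @return data.frame `decade`, `n_dedicated`.
#' @export
count_dedicated_authors <- function(scores, s_threshold = 50,
                                    decades = DECADES_DEFAULT) {
  n <- vapply(decades, function(d) {
    sum(scores$decade == d & scores$score > s_threshold, na.rm = TRUE)
  }, 1L)
  data.frame(decade = decades, n_dedicated = unname(n),
             stringsAsFactors = FALSE)
}

#' Correct a global species-richness estimate for one dark taxon
#'
#' Ratio-based global richness extrapolations assume a focal family holds a
#' share `p_assumed` of described regional diversity; if standardized
#' sampling shows its true share is `p_observed`, the unsampled gap
#' `p_observed - p_assumed` is missing from the extrapolation base, and
#' each endpoint is corrected to `x / (1 - (p_observed - p_assumed))`.
#' With the British-fauna shares for gall midges (2.7% assumed, 20%
#' observed) this shifts 5.4-7.2 million to 6.5-8.7 million species.
#'
#' @param low,high estimate endpoints (million species), `low <= high`.
#' @param p_assumed share assumed in the original extrapolation.
#' @param p_observed share observed under standardized sampling.
#' @param digits rounding (half away from zero) for the reported values.
#' @return list with `low`, `high` (corrected, rounded) and `divisor`.
#' @export
rescale_global_richness <- function(low, high, p_assumed = 0.027,
                                    p_observed = 0.20, digits = 1L) {
  stopifnot(low <= high, p_assumed >= 0, p_observed < 1)
  if (p_observed <= p_assumed) {
    warning("observed share does not exceed assumed share; ",
            "estimate unchanged")
    return(list(low = round_half_away(low, digits),
                high = round_half_away(high, digits), divisor = 1))
  }
  divisor <- 1 - (p_observed - p_assumed)
  list(low = round_half_away(low / divisor, digits),
       high = round_half_away(high / divisor, digits),
       divisor = divisor)
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
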