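#' Is an effector reversed towards recovery?
#'
#' An effector counts as reversed when its predicted activity has the sign
#' opposite to its disease sign and magnitude at least `epsilon`
#' (default 0.1, boundary inclusive). Activity exactly 0 is neither
#' reversed nor anti-reversed.
#'
#' @param activity predicted activity in \[-1, 1\] (vectorised).
#' @param disease_sign +1 or -1 per effector.
#' @param epsilon minimum magnitude, > 0.
#' @return Logical vector.
#' @export
is_reversed <- function(activity, disease_sign, epsilon = 0.1) {
  stopifnot(epsilon > 0, all(disease_sign %in% c(-1, 1)))
  abs(activity) >= epsilon & activity * disease_sign < 0
}

#' Mean signed reversion strength over a motive (T-Signal)
#'
#' Global measure of output signal: the mean over the motive's effectors of
#' minus the disease sign times the predicted activity. Positive values
#' mean net reversion towards recovery; the measure is odd in the profile
#' and bounded in \[-1, 1\].
#'
#' @param profile named numeric activity profile.
#' @param motive one motive from a [disease_characterization()].
#' @return Numeric scalar.
#' @export
t_signal <- function(profile, motive) {
  a <- profile[motive$effectors$protein]
  if (anyNA(a)) stop("profile does not cover all effectors of motive '",
                     motive$name, "'")
  mean(-motive$effectors$sign * a)
}

#' Weighted global intensity score (W-Signal)
#'
#' Composite intensity that ponders effectors correctly (`n_eff`) versus
#' incorrectly (`n_anti`) activated over the motive size:
#' \deqn{W = \frac{1 + \#Eff}{1 + \#\text{-}Eff} \cdot \frac{\#Eff}{BED_p} + T}
#' It reduces to the T-Signal when no effector is reversed, grows strictly
#' with `n_eff` and shrinks strictly with `n_anti` (for `n_eff` >= 1).
#'
#' @param n_eff number of reversed effectors.
#' @param n_anti number of effectors pushed further in the disease
#'   direction with magnitude >= epsilon.
#' @param bed_p total number of effectors in the motive definition (>= 1).
#' @param t_signal the motive's T-Signal.
#' @return Numeric scalar.
#' @export
w_signal <- function(n_eff, n_anti, bed_p, t_signal) {
  stopifnot(bed_p >= 1, n_eff >= 0, n_anti >= 0, n_eff + n_anti <= bed_p)
  (1 + n_eff) / (1 + n_anti) * (n_eff / bed_p) + t_signal
}

#' Motive-level impact summary
#'
#' Counts reversed (`n_eff`) and anti-reversed (`n_anti`) effectors at
#' magnitude `epsilon`, and reports `pct_reversed` = 100 n_eff / BED_p,
#' the T-Signal and the W-Signal.
#'
#' @param profile named numeric activity profile covering the motive.
#' @param motive one motive from a [disease_characterization()].
#' @param epsilon reversal magnitude threshold (default 0.1).
#' @return A one-row data.frame: `motive`, `n_eff`, `n_anti`, `bed_p`,
#'   `pct_reversed`, `t_signal`, `w_signal`.
#' @export
motive_impact <- function(profile, motive, epsilon = 0.1) {
  if (is.null(motive$effectors) || nrow(motive$effectors) == 0L)
    stop("motive has no effectors")
  a <- profile[motive$effectors$protein]
  if (anyNA(a)) stop("profile does not cover all effectors of motive '",
                     motive$name, "'")
  sg <- motive$effectors$sign
  n_eff <- sum(is_reversed(a, sg, epsilon))
  n_anti <- sum(abs(a) >= epsilon & a * sg > 0)
  bed_p <- nrow(motive$effectors)
  ts <- t_signal(profile, motive)
  data.frame(motive = motive$name,
             n_eff = n_eff, n_anti = n_anti, bed_p = bed_p,
             pct_reversed = 100 * n_eff / bed_p,
             t_signal = ts,
             w_signal = w_signal(n_eff, n_anti, bed_p, ts),
             stringsAsFactors = FALSE)
}

#' Impact table over all motives of a characterization
#'
#' @param profile named numeric activity profile.
#' @param char a [disease_characterization()].
#' @param epsilon reversal magnitude threshold.
#' @param roles motive roles to include (default: all).
#' @return data.frame with one row per motive, as [motive_impact()].
#' @export
impact_table <- function(profile, char, epsilon = 0.1,
                         roles = c("response", "basal", "context")) {
  stopifnot(inherits(char, "disease_characterization"))
  keep <- Filter(function(m) m$role %in% roles, char$motives)
  do.call(rbind, lapply(keep, motive_impact, profile = profile,
                        epsilon = epsilon))
}

#' Joint stimulus of a drug combination
#'
#' Union of both drugs' clamped target values. Shared targets with the
#' same sign merge (drug + itself is idempotent); a shared target with
#' conflicting signs is an error. The combined bioflag constraints are
#' attached as attribute `"bioflags"` for reporting.
#'
#' @param drug_a,drug_b [drug_profile()] objects.
#' @param char optional [disease_characterization()]; when given, its basal
#'   motive initialises the basal state.
#' @return A [stimulus()].
#' @export
combination_stimulus <- function(drug_a, drug_b, char = NULL) {
  stopifnot(inherits(drug_a, "drug_profile"), inherits(drug_b, "drug_profile"))
  ta <- setNames(as.numeric(drug_a$targets$sign), drug_a$targets$protein)
  tb <- setNames(as.numeric(drug_b$targets$sign), drug_b$targets$protein)
  shared <- intersect(names(ta), names(tb))
  conflict <- shared[ta[shared] != tb[shared]]
  if (length(conflict))
    stop("conflicting target sign for: ", paste(conflict, collapse = ", "))
  clamped <- c(ta, tb[setdiff(names(tb), names(ta))])
  st <- stimulus(clamped = clamped,
                 basal = if (is.null(char)) numeric() else basal_values(char))
  flags <- rbind(drug_a$bioflags, drug_b$bioflags)
  attr(st, "bioflags") <- flags[!duplicated(flags$protein), , drop = FALSE]
  st
}

#' Stimulus of a single drug
#'
#' Drug targets clamped at their effect sign; the characterization's basal
#' motive, if given, initialises the basal state.
#'
#' @param drug a [drug_profile()].
#' @param char optional [disease_characterization()].
#' @return A [stimulus()].
#' @export
drug_stimulus <- function(drug, char = NULL) {
  stopifnot(inherits(drug, "drug_profile"))
  stimulus(clamped = setNames(as.numeric(drug$targets$sign),
                              drug$targets$protein),
           basal = if (is.null(char)) numeric() else basal_values(char))
}

#' Synergy call from single-drug and combination W-Signals
#'
#' The combination is synergistic iff its W-Signal strictly exceeds both
#' single-drug W-Signals; otherwise it is additive or sub-additive. The
#' call is symmetric in the two drugs.
#'
#' @param w_a,w_b W-Signal of each drug alone.
#' @param w_ab W-Signal of the combination.
#' @return A one-row data.frame: `w_a`, `w_b`, `w_ab`, `label`.
#' @export
assess_synergy <- function(w_a, w_b, w_ab) {
  label <- if (w_ab > max(w_a, w_b)) "synergistic" else "additive-or-sub-additive"
  data.frame(w_a = w_a, w_b = w_b, w_ab = w_ab, label = label,
             stringsAsFactors = FALSE)
}

#' Which drug modulates a protein?
#'
#' Classifies a protein by its mean activity under two drugs at a
#' modulation threshold (default |0.3|, also used for the between-drug
#' difference): `both` when both magnitudes reach the threshold and the
#' drugs differ by less than it; `drug_a`/`drug_b` when only that drug
#' reaches it, or both do but differ by at least the threshold and that
#' drug's magnitude is strictly larger; `neither` otherwise.
#'
#' @param mean_a,mean_b mean ensemble activity under each drug
#'   (vectorised).
#' @param thr modulation threshold, > 0 (default 0.3).
#' @return Character vector in `c("drug_a", "drug_b", "both", "neither")`.
#' @export
modulation_class <- function(mean_a, mean_b, thr = 0.3) {
  stopifnot(thr > 0, length(mean_a) == length(mean_b))
  out <- rep("neither", length(mean_a))
  a_on <- abs(mean_a) >= thr
  b_on <- abs(mean_b) >= thr
  close <- abs(mean_a - mean_b) < thr
  out[a_on & b_on & close] <- "both"
  out[a_on & (!b_on | (!close & abs(mean_a) > abs(mean_b)))] <- "drug_a"
  out[b_on & (!a_on | (!close & abs(mean_b) > abs(mean_a)))] <- "drug_b"
  out
}

#' Per-protein effector modulation table
#'
#' The data behind an effector heatmap: per protein, the mean activity
#' under each drug, its disease sign, motive memberships, and the
#' modulation class.
#'
#' @param profile_a,profile_b named numeric ensemble profiles for the two
#'   drugs.
#' @param char a [disease_characterization()].
#' @param thr modulation threshold (default 0.3).
#' @return data.frame with columns `protein`, `mean_a`, `mean_b`,
#'   `disease_sign`, `motives`, `modulation`.
#' @export
effector_heatmap_table <- function(profile_a, profile_b, char, thr = 0.3) {
  stopifnot(inherits(char, "disease_characterization"))
  prots <- unique_effectors(char)
  memb <- vapply(prots, function(p) {
    paste(vapply(Filter(function(m) p %in% m$effectors$protein, char$motives),
                 `[[`, "", "name"), collapse = ";")
  }, "")
  sign1 <- vapply(prots, function(p) {
    for (m in char$motives) {
      i <- match(p, m$effectors$protein)
      if (!is.na(i)) return(m$effectors$sign[i])
    }
    NA_integer_
  }, integer(1))
  a <- profile_a[prots]
  b <- profile_b[prots]
  data.frame(protein = prots,
             mean_a = as.numeric(a), mean_b = as.numeric(b),
             disease_sign = sign1,
             motives = memb,
             modulation = modulation_class(as.numeric(a), as.numeric(b), thr),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write an impact table as TSV
#'
#' @param impacts data.frame from [impact_table()], optionally with a
#'   `treatment` column prepended by the caller.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_impact_table <- function(impacts, path) {
  write.table(impacts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
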