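#' Edge-weighting parameters
#'
#' Edges of the transfer graph are weighted by
#' \deqn{W_{ij} = \alpha\,(1 - sim(v_i, v_j)) + (1 - \alpha)\,(shift + f_e(r_{ij})) / scale}
#' where `sim` is the structural similarity of the two compounds in \[0, 1\],
#' `f_e` is the reaction's Gibbs free energy change \eqn{\Delta G'_r}, and
#' `shift = 3200`, `scale = 10000` rescale the tabulated energies (whose
#' published extremes are -2233.7 and 10194.7) into \[0.09663, 1.33947\], the
#' same order of magnitude as the similarity term.
#'
#' @param alpha Blend in \[0, 1\]: 1 = similarity only, 0 = thermodynamics
#'   only, 0.5 = both. `NA` selects unweighted mode (every edge weight 1).
#' @param shift,scale Normalization constants; override only for energy
#'   tables on a different scale.
#' @param missing_energy Policy for reactions with no tabulated energy:
#'   a number to substitute (default 0, i.e. normalized 0.32), or the string
#'   `"exclude"` to drop such edges from the graph.
#' @return An object of class `weight_params`.
#' @export
weight_params <- function(alpha = 0.5, shift = 3200, scale = 10000,
                          missing_energy = 0) {
  if (!is.na(alpha) && (alpha < 0 || alpha > 1)) {
    abort_config("`alpha` must be in [0, 1] (or NA for unweighted mode).")
  }
  if (!identical(missing_energy, "exclude") &&
      !(is.numeric(missing_energy) && length(missing_energy) == 1L &&
        is.finite(missing_energy))) {
    abort_config("`missing_energy` must be a finite number or \"exclude\".")
  }
  stopifnot(is.numeric(shift), is.numeric(scale), scale > 0)
  structure(list(alpha = as.numeric(alpha), shift = shift, scale = scale,
                 missing_energy = missing_energy),
            class = "weight_params")
}

#' Map the similarity/thermodynamics switches to the blend parameter
#'
#' The search exposes two boolean switches: `sc` (drive by compound
#' similarity) and `td` (drive by thermodynamic feasibility). They select the
#' blend: both on gives `alpha = 0.5`, similarity only gives `alpha = 1`,
#' thermodynamics only gives `alpha = 0`. Both off is an extension not
#' covered by the weighting scheme: it returns `NA`, meaning unit edge
#' weights (pure hop-count search).
#'
#' @param sc,td Logical switches.
#' @return `alpha` as a single numeric (or `NA` for unweighted mode).
#' @examples
#' psi_to_alpha(TRUE, TRUE)   # 0.5
#' psi_to_alpha(TRUE, FALSE)  # 1
#' psi_to_alpha(FALSE, TRUE)  # 0
#' @export
psi_to_alpha <- function(sc, td) {
  stopifnot(is.logical(sc), is.logical(td), length(sc) == 1L, length(td) == 1L)
  if (sc && td) 0.5 else if (sc) 1.0 else if (td) 0.0 else NA_real_
}

#' Compute the weight of one reaction edge
#'
#' @param sim_value Similarity score(s) in \[0, 1\].
#' @param fe_value \eqn{\Delta G'_r} value(s); `NA` means missing and is
#'   handled by the `missing_energy` policy of `params` (substitute a value,
#'   or `"exclude"`, in which case `NA` is returned so callers can drop the
#'   edge).
#' @param params A [weight_params()].
#' @return Nonnegative weight(s); a pathological energy below `-shift` is
#'   clamped to 0 with a warning.
#' @examples
#' p <- weight_params(alpha = 0.5)
#' edge_weight(0.375, -64.5, p)  # 0.469275
#' edge_weight(0.8, -19.9, p)    # 0.259005
#' @export
edge_weight <- function(sim_value, fe_value, params = weight_params()) {
  stopifnot(inherits(params, "weight_params"))
  if (any(is.na(sim_value)) || any(sim_value < 0 | sim_value > 1)) {
    abort_domain("`sim_value` must lie in [0, 1].")
  }
  n <- max(length(sim_value), length(fe_value))
  sim_value <- rep_len(sim_value, n)
  fe_value <- rep_len(as.numeric(fe_value), n)
  if (is.na(params$alpha)) return(rep(1, n))
  miss <- is.na(fe_value)
  if (any(miss)) {
    if (identical(params$missing_energy, "exclude")) {
      out <- rep(NA_real_, n)
      if (all(miss)) return(out)
    } else {
      fe_value[miss] <- params$missing_energy
    }
  }
  a <- params$alpha
  w <- a * (1 - sim_value) + (1 - a) * (params$shift + fe_value) / params$scale
  neg <- !is.na(w) & w < 0
  if (any(neg)) {
    warn(sprintf("%d edge weight(s) below 0 (dG'r < -%g); clamped to 0.",
                 sum(neg), params$shift))
    w[neg] <- 0
  }
  if (identical(params$missing_energy, "exclude")) w[miss] <- NA_real_
  w
}

#' Range of the normalized energy term
#'
#' Maps an interval of raw \eqn{\Delta G'_r} values through the
#' normalization `(shift + fe) / scale`. With the default constants the
#' tabulated extremes \[-2233.7, 10194.7\] map to \[0.09663, 1.33947\].
#'
#' @param fe_min,fe_max Interval endpoints, `fe_min <= fe_max`.
#' @param params A [weight_params()].
#' @return Numeric vector `c(low, high)`.
#' @export
normalized_energy_range <- function(fe_min, fe_max, params = weight_params()) {
  stopifnot(fe_min <= fe_max)
  c((params$shift + fe_min) / params$scale,
    (params$shift + fe_max) / params$scale)
}
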