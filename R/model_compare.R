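#' Demographic model comparison by AIC
#'
#' Consumes a table of demographic-model fits (log-likelihood, free-
#' parameter count, diffusion-unit parameter values as produced by
#' SFS-based demographic inference), ranks models by Akaike's information
#' criterion, and converts diffusion-scaled parameters into natural units
#' given a mutation rate, generation time and callable sequence length.
#' Likelihood optimization itself is out of scope: fits are inputs.
#'
#' Diffusion conventions used throughout: theta = 4 N_anc mu L; population
#' sizes are nu_i N_anc; the time unit is 2 N_anc generations; migration
#' parameters divide by 2 N_anc to give per-generation fractions.
#'
#' @name model_compare
NULL

#' Akaike information criterion
#'
#' @param log_likelihood maximized log-likelihood (natural log).
#' @param k number of free parameters (>= 0).
#' @return 2k - 2 log_likelihood.
#' @export
aic <- function(log_likelihood, k) {
  stopifnot(all(k >= 0))
  2 * k - 2 * log_likelihood
}

#' A demographic model fit
#'
#' @param name model label.
#' @param log_likelihood maximized log-likelihood.
#' @param k number of free parameters (should equal the number of
#'   optimized entries in `params`).
#' @param params named numeric vector of diffusion-unit parameters
#'   (e.g. theta, nu1, nu2, m12, m21, T, misid).
#' @return list of class `model_fit` with `aic` filled in.
#' @export
model_fit <- function(name, log_likelihood, k, params = numeric()) {
  structure(list(name = name, log_likelihood = log_likelihood,
                 k = as.integer(k), params = params,
                 aic = aic(log_likelihood, k)),
            class = "model_fit")
}

#' Rank model fits by AIC
#'
#' Ascending AIC with delta-AIC relative to the best; ties broken in favor
#' of fewer parameters (parsimony).
#'
#' @param fits list of [model_fit()] objects (>= 2).
#' @return data.frame: `model`, `log_likelihood`, `k`, `aic`, `delta_aic`,
#'   best first.
#' @export
rank_models <- function(fits) {
  if (length(fits) < 2) stop("rank_models needs at least two fits")
  tab <- data.frame(
    model = vapply(fits, `[[`, character(1), "name"),
    log_likelihood = vapply(fits, `[[`, numeric(1), "log_likelihood"),
    k = vapply(fits, `[[`, integer(1), "k"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$aic, tab$k), ]
  tab$delta_aic <- tab$aic - tab$aic[1]
  rownames(tab) <- NULL
  tab
}

#' Convert diffusion-scaled parameters to natural units
#'
#' N_anc = theta / (4 mu L); sizes nu_i N_anc diploids; times
#' 2 N_anc T_diffusion generations (and years via the generation time);
#' migration m_diffusion / (2 N_anc) per generation. Parameters are
#' recognized by name: `theta`; `nu*` (sizes); `T*` (times); `m*`
#' (migration); anything else (e.g. `misid`, `s`) passes through.
#'
#' @param fit a [model_fit()]; must carry `theta` in `params` unless
#'   `N_anc` is given.
#' @param mutation_rate per-site per-generation mutation rate.
#' @param generation_time generation time in years.
#' @param sequence_length callable sites L.
#' @param N_anc optionally override the ancestral size directly.
#' @return named list of natural-unit values: `N_anc`, one `N_<nu-name>`
#'   per size, `<T-name>_generations` and `<T-name>_years` per time,
#'   `<m-name>_per_generation` per migration rate, plus pass-through
#'   parameters unchanged.
#' @export
scale_to_natural_units <- function(fit, mutation_rate, generation_time,
                                   sequence_length, N_anc = NULL) {
  if (is.null(N_anc)) {
    if (!("theta" %in% names(fit$params)))
      stop("fit lacks theta and no N_anc was given")
    if (missing(mutation_rate) || missing(sequence_length) ||
        is.null(mutation_rate) || is.null(sequence_length))
      stop("mutation_rate and sequence_length are required to scale theta")
    N_anc <- fit$params[["theta"]] / (4 * mutation_rate * sequence_length)
  }
  out <- list(N_anc = N_anc)
  for (nm in names(fit$params)) {
    v <- fit$params[[nm]]
    if (nm == "theta") next
    if (grepl("^nu", nm)) {
      out[[paste0("N_", nm)]] <- v * N_anc
    } else if (grepl("^T", nm)) {
      gens <- 2 * N_anc * v
      out[[paste0(nm, "_generations")]] <- gens
      out[[paste0(nm, "_years")]] <- gens * generation_time
    } else if (grepl("^m", nm) && nm != "misid") {
      out[[paste0(nm, "_per_generation")]] <- v / (2 * N_anc)
    } else {
      out[[nm]] <- v
    }
  }
  out
}

#' Invert natural-unit scaling back to diffusion units
#'
#' Round-trip companion of [scale_to_natural_units()]; used for checking
#' scaling consistency.
#'
#' @param natural output list of [scale_to_natural_units()].
#' @param mutation_rate,generation_time,sequence_length as there.
#' @return named numeric vector of diffusion-unit parameters (incl. theta).
#' @export
scale_to_diffusion_units <- function(natural, mutation_rate, generation_time,
                                     sequence_length) {
  N_anc <- natural$N_anc
  out <- c(theta = 4 * N_anc * mutation_rate * sequence_length)
  for (nm in names(natural)) {
    if (nm == "N_anc") next
    v <- natural[[nm]]
    if (grepl("^N_nu", nm)) {
      out[sub("^N_", "", nm)] <- v / N_anc
    } else if (grepl("_generations$", nm)) {
      out[sub("_generations$", "", nm)] <- v / (2 * N_anc)
    } else if (grepl("_years$", nm)) {
      next  # redundant with _generations
    } else if (grepl("_per_generation$", nm)) {
      out[sub("_per_generation$", "", nm)] <- v * 2 * N_anc
    } else {
      out[nm] <- v
    }
  }
  out
}

#' Read a model-fit table
#'
#' TSV with header `model  ll  k  params`, where `params` is
#' `name=value;name=value;...` in diffusion units.
#'
#' @param path file path.
#' @return list of [model_fit()] objects.
#' @export
read_model_fits <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    kv <- strsplit(strsplit(tab$params[i], ";")[[1]], "=")
    params <- stats::setNames(vapply(kv, function(x) as.numeric(x[2]),
                                     numeric(1)),
                              vapply(kv, `[[`, character(1), 1))
    model_fit(tab$model[i], tab$ll[i], tab$k[i], params)
  })
}
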