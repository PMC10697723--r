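## Constraint-based model engine: measured exchange bounds, HA-maximization
## LP, constraint-resampled flux ensembles, and condition comparison.

#' Build an FBA constraint set from measured exchange rates
#'
#' Converts per-cell exchange rates (fmol/cell/h, positive = secretion) into
#' model-unit flux bounds (mmol/gDW/h) and assembles the constraint set for
#' [solve_fba()] / [ensemble_fba()]. Each non-omitted measured metabolite
#' gets an exchange bound of `rate +/- k * sd`, intersected with the default
#' network bounds; the omitted amino acids (see [omitted_amino_acids()])
#' keep their default bounds. The measured growth rate becomes a lower bound
#' on the growth reaction, and an oxygen consumption rate (OCR, positive
#' number in fmol O2/cell/h) bounds the O2 exchange.
#'
#' @param rates data.frame with columns `metabolite`, `rate` and `sd`
#'   (fmol/cell/h), e.g. from [exchange_rates()].
#' @param net a `metabolic_network`.
#' @param omit metabolite names to leave unconstrained; defaults to the eight
#'   amino acids omitted for LP convergence.
#' @param k half-width of the bound in SD units (default 1).
#' @param gdw_per_cell cell dry mass in grams (default 4e-10, i.e. 400 pg).
#' @param growth_rate,growth_sd measured growth rate (1/h) and its SD; the
#'   growth reaction is bounded to `growth_rate +/- k * growth_sd` (lower
#'   bound floored at 0).
#' @param ocr,ocr_sd oxygen consumption rate and SD (fmol O2/cell/h,
#'   positive = consumption).
#' @return a `constraint_set`: list with `exchanges` (data.frame of reaction,
#'   metabolite, model-unit rate, sd, lb, ub, omitted flag), `growth_bounds`,
#'   `o2_bounds`, and the conversion factor used.
#' @export
build_constraints <- function(rates, net, omit = omitted_amino_acids(),
                              k = 1, gdw_per_cell = 4e-10,
                              growth_rate = NULL, growth_sd = 0,
                              ocr = NULL, ocr_sd = 0) {
  stopifnot(inherits(net, "metabolic_network"),
            all(c("metabolite", "rate", "sd") %in% names(rates)))
  conv <- 1e-12 / gdw_per_cell   # fmol/cell/h -> mmol/gDW/h
  measured <- rates$metabolite
  non_omitted <- setdiff(measured, omit)
  missing_ex <- setdiff(non_omitted, names(net$exchange_map))
  if (length(missing_ex))
    stop("measured metabolites with no exchange reaction in the network: ",
         paste(missing_ex, collapse = ", "))

  keep <- rates$metabolite %in% non_omitted
  ex <- data.frame(
    metabolite = rates$metabolite[keep],
    reaction = unname(net$exchange_map[rates$metabolite[keep]]),
    rate = rates$rate[keep] * conv,
    sd = rates$sd[keep] * conv,
    stringsAsFactors = FALSE)
  ex$lb <- pmax(ex$rate - k * ex$sd, net$lb[ex$reaction])
  ex$ub <- pmin(ex$rate + k * ex$sd, net$ub[ex$reaction])
  ex$omitted <- FALSE
  om <- rates$metabolite %in% intersect(measured, omit)
  if (any(om)) {
    omdf <- data.frame(metabolite = rates$metabolite[om],
                       reaction = unname(net$exchange_map[rates$metabolite[om]]),
                       rate = rates$rate[om] * conv, sd = rates$sd[om] * conv,
                       lb = NA_real_, ub = NA_real_, omitted = TRUE,
                       stringsAsFactors = FALSE)
    ex <- rbind(ex, omdf)
  }

  growth_bounds <- NULL
  if (!is.null(growth_rate))
    growth_bounds <- c(mean = growth_rate, sd = growth_sd,
                       lb = max(growth_rate - k * growth_sd, 0),
                       ub = growth_rate + k * growth_sd)
  o2_bounds <- NULL
  if (!is.null(ocr)) {
    o2r <- tagged_reaction(net, "o2_exchange")
    rate_m <- -ocr * conv          # consumption -> negative exchange flux
    o2_bounds <- c(mean = rate_m, sd = ocr_sd * conv,
                   lb = max(rate_m - k * ocr_sd * conv, net$lb[[o2r]]),
                   ub = min(rate_m + k * ocr_sd * conv, net$ub[[o2r]]))
  }
  structure(list(exchanges = ex, growth_bounds = growth_bounds,
                 o2_bounds = o2_bounds, k = k, conv = conv,
                 omit = omit, network_id = net$id),
            class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  nco <- sum(!x$exchanges$omitted)
  cat("FBA constraint set:", nco, "constrained exchanges,",
      sum(x$exchanges$omitted), "measured-but-omitted\n")
  if (!is.null(x$growth_bounds))
    cat(sprintf("growth in [%.4g, %.4g] 1/h\n",
                x$growth_bounds[["lb"]], x$growth_bounds[["ub"]]))
  if (!is.null(x$o2_bounds))
    cat(sprintf("O2 exchange in [%.4g, %.4g] mmol/gDW/h\n",
                x$o2_bounds[["lb"]], x$o2_bounds[["ub"]]))
  invisible(x)
}

## Return a copy of the network with a constraint set applied to its bounds.
apply_constraints <- function(net, constraints = NULL) {
  if (is.null(constraints)) return(net)
  stopifnot(inherits(constraints, "constraint_set"))
  ex <- constraints$exchanges[!constraints$exchanges$omitted, , drop = FALSE]
  net$lb[ex$reaction] <- ex$lb
  net$ub[ex$reaction] <- ex$ub
  if (!is.null(constraints$growth_bounds)) {
    g <- tagged_reaction(net, "growth")
    net$lb[[g]] <- constraints$growth_bounds[["lb"]]
    net$ub[[g]] <- constraints$growth_bounds[["ub"]]
  }
  if (!is.null(constraints$o2_bounds)) {
    o <- tagged_reaction(net, "o2_exchange")
    net$lb[[o]] <- constraints$o2_bounds[["lb"]]
    net$ub[[o]] <- constraints$o2_bounds[["ub"]]
  }
  if (any(net$lb > net$ub))
    stop("constraint application produced lb > ub for ",
         paste(net$reactions[net$lb > net$ub], collapse = ", "))
  net
}

#' Solve the flux balance analysis LP
#'
#' Maximizes the objective reaction's flux subject to steady state
#' (`S v = 0`) and the network's (optionally constrained) bounds. Because LP
#' optima are generally non-unique, a parsimonious second stage minimizes the
#' total absolute flux `sum(|v|)` at the fixed optimal objective so that
#' reported per-reaction fluxes are well defined.
#'
#' @param net a `metabolic_network`.
#' @param constraints optional `constraint_set` from [build_constraints()].
#' @param objective reaction tag or id to maximize (default "ha_synthesis").
#' @param parsimonious run the flux-minimizing second stage (default TRUE).
#' @return an `fba_solution`: list with `status` ("optimal", "infeasible" or
#'   "unbounded"), `objective_value`, named `fluxes`, and `objective_reaction`.
#' @examples
#' sol <- solve_fba(toy_core_network())
#' sol$objective_value
#' @export
solve_fba <- function(net, constraints = NULL, objective = "ha_synthesis",
                      parsimonious = TRUE) {
  net <- apply_constraints(net, constraints)
  obj_rxn <- if (objective %in% net$reactions) objective else
    tagged_reaction(net, objective)
  if (length(obj_rxn) != 1L)
    stop("objective '", objective, "' does not identify a unique reaction")
  n <- length(net$reactions)
  cc <- as.numeric(net$reactions == obj_rxn)
  sol <- lp_solve(cc, net$S, rep(0, nrow(net$S)), net$lb, net$ub)
  if (sol$status != "optimal")
    return(structure(list(status = sol$status, objective_value = NA_real_,
                          fluxes = NULL, objective_reaction = obj_rxn),
                     class = "fba_solution"))
  zstar <- sol$objective
  fluxes <- stats::setNames(sol$x, net$reactions)
  if (parsimonious) {
    ## split v = p - m with negative parts only for reactions that can run
    ## backwards; minimize sum(p + m) at c'v = z*
    lb <- net$lb; ub <- net$ub
    rev_idx <- which(lb < 0)
    plb <- pmax(lb, 0); pub <- pmax(ub, 0)
    mlb <- pmax(-ub[rev_idx], 0); mub <- -lb[rev_idx]
    A2 <- rbind(cbind(net$S, -net$S[, rev_idx, drop = FALSE]),
                c(cc, -cc[rev_idx]))
    b2 <- c(rep(0, nrow(net$S)), zstar)
    nr <- length(rev_idx)
    s2 <- lp_solve(rep(-1, n + nr), A2, b2, c(plb, mlb), c(pub, mub),
                   maximize = TRUE)
    if (s2$status == "optimal") {
      v <- s2$x[seq_len(n)]
      v[rev_idx] <- v[rev_idx] - s2$x[n + seq_len(nr)]
      fluxes <- stats::setNames(v, net$reactions)
    }
  }
  structure(list(status = "optimal", objective_value = zstar,
                 fluxes = fluxes, objective_reaction = obj_rxn),
            class = "fba_solution")
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("FBA solution (", x$status, "): ", x$objective_reaction, " = ",
      format(x$objective_value, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Constraint-resampled FBA ensemble
#'
#' Runs `n` FBA solves in which the center of every measured exchange bound
#' (and of the growth and O2 bounds, when present) is redrawn from a normal
#' distribution truncated to the default network bounds, with SD equal to the
#' measurement SD; each draw keeps the `+/- k * SD` band of its constraint
#' set. This represents the propagation of metabolomics measurement
#' uncertainty through the LP. Draws whose LP is infeasible are counted and
#' dropped.
#'
#' @param net a `metabolic_network`.
#' @param constraints a `constraint_set`.
#' @param n number of simulations (default 1000).
#' @param seed integer seed; the ensemble is bit-reproducible for a fixed
#'   seed.
#' @param objective,parsimonious passed to [solve_fba()].
#' @param condition label stored with the ensemble.
#' @return an `fba_ensemble`: list with `condition`, `n_runs`,
#'   `fluxes` (matrix, optimal runs x reactions), `objective_values`,
#'   `infeasible_count`, `seed`.
#' @export
ensemble_fba <- function(net, constraints, n = 1000, seed = 1,
                         objective = "ha_synthesis", parsimonious = TRUE,
                         condition = "condition") {
  stopifnot(inherits(constraints, "constraint_set"))
  ex <- constraints$exchanges
  kk <- constraints$k
  with_seed(seed, {
    rows <- vector("list", n)
    objs <- rep(NA_real_, n)
    infeasible <- 0L
    for (i in seq_len(n)) {
      cs_i <- constraints
      act <- !ex$omitted
      ctr <- rep(NA_real_, nrow(ex))
      for (j in which(act)) {
        ctr[j] <- rtruncnorm(1, ex$rate[j], ex$sd[j],
                             net$lb[[ex$reaction[j]]], net$ub[[ex$reaction[j]]])
      }
      cs_i$exchanges$lb[act] <- pmax(ctr[act] - kk * ex$sd[act],
                                     net$lb[ex$reaction[act]])
      cs_i$exchanges$ub[act] <- pmin(ctr[act] + kk * ex$sd[act],
                                     net$ub[ex$reaction[act]])
      if (!is.null(cs_i$growth_bounds)) {
        g <- cs_i$growth_bounds
        gc <- rtruncnorm(1, g[["mean"]], g[["sd"]], 0, Inf)
        cs_i$growth_bounds[["lb"]] <- max(gc - kk * g[["sd"]], 0)
        cs_i$growth_bounds[["ub"]] <- gc + kk * g[["sd"]]
      }
      if (!is.null(cs_i$o2_bounds)) {
        o <- cs_i$o2_bounds
        o2r <- tagged_reaction(net, "o2_exchange")
        oc <- rtruncnorm(1, o[["mean"]], o[["sd"]], net$lb[[o2r]], net$ub[[o2r]])
        cs_i$o2_bounds[["lb"]] <- max(oc - kk * o[["sd"]], net$lb[[o2r]])
        cs_i$o2_bounds[["ub"]] <- min(oc + kk * o[["sd"]], net$ub[[o2r]])
      }
      sol <- tryCatch(solve_fba(net, cs_i, objective = objective,
                                parsimonious = parsimonious),
                      error = function(e) list(status = "infeasible"))
      if (identical(sol$status, "optimal")) {
        rows[[i]] <- sol$fluxes
        objs[i] <- sol$objective_value
      } else infeasible <- infeasible + 1L
    }
    ok <- !vapply(rows, is.null, logical(1))
    fx <- if (any(ok)) do.call(rbind, rows[ok]) else
      matrix(numeric(0), 0, length(net$reactions),
             dimnames = list(NULL, net$reactions))
    if (infeasible > n / 2)
      warning("more than half of the ensemble draws were infeasible (",
              infeasible, "/", n, "); measured bounds may be inconsistent ",
              "with the network")
    tag_map <- stats::setNames(
      vapply(bioenergetic_tags(),
             function(t) tagged_reaction(net, t)[1], character(1)),
      bioenergetic_tags())
    structure(list(condition = condition, n_runs = n, fluxes = fx,
                   objective_values = objs[ok],
                   infeasible_count = infeasible, seed = seed,
                   network_id = net$id, tag_map = tag_map[!is.na(tag_map)]),
              class = "fba_ensemble")
  })
}

#' @export
print.fba_ensemble <- function(x, ...) {
  cat("FBA ensemble '", x$condition, "': ", nrow(x$fluxes), "/", x$n_runs,
      " optimal runs (", x$infeasible_count, " infeasible), seed ", x$seed,
      "\n", sep = "")
  if (length(x$objective_values))
    cat(sprintf("objective: mean %.5g, sd %.3g\n",
                mean(x$objective_values), stats::sd(x$objective_values)))
  invisible(x)
}

#' @export
summary.fba_ensemble <- function(object, ...) {
  data.frame(reaction = colnames(object$fluxes),
             mean = colMeans(object$fluxes),
             sd = apply(object$fluxes, 2, stats::sd),
             row.names = NULL)
}

## Default bioenergetic reaction subset used for condition comparisons
bioenergetic_tags <- function() {
  c("upper_glycolysis", "pyr_to_lac", "glu_to_akg", "akg_to_succoa",
    "atp_demand", "ha_synthesis", "o2_exchange")
}

#' Compare two FBA ensembles over a reaction subset
#'
#' Per-reaction ensemble mean, SD, difference of means (A - B) and a
#' direction flag over a subset of reactions; by default the tagged
#' bioenergetic subset (upper glycolysis, pyruvate -> lactate, glutamate ->
#' alpha-ketoglutarate, alpha-KG -> succinyl-CoA, ATP demand, HA synthesis,
#' O2 exchange).
#'
#' @param ens_a,ens_b `fba_ensemble` objects from the same network.
#' @param reactions reaction ids or tags; NULL for the bioenergetic subset.
#' @return data.frame with columns `reaction`, `mean_a`, `sd_a`, `mean_b`,
#'   `sd_b`, `difference` and `direction` ("higher_in_a", "higher_in_b",
#'   "equal").
#' @export
compare_flux_conditions <- function(ens_a, ens_b, reactions = NULL) {
  stopifnot(inherits(ens_a, "fba_ensemble"), inherits(ens_b, "fba_ensemble"))
  if (!identical(ens_a$network_id, ens_b$network_id))
    stop("ensembles come from different networks: ",
         ens_a$network_id, " vs ", ens_b$network_id)
  if (!identical(colnames(ens_a$fluxes), colnames(ens_b$fluxes)))
    stop("ensembles have mismatched reaction sets")
  all_r <- colnames(ens_a$fluxes)
  if (is.null(reactions)) reactions <- bioenergetic_tags()
  ids <- vapply(reactions, function(r) {
    if (r %in% all_r) r
    else if (r %in% names(ens_a$tag_map)) unname(ens_a$tag_map[[r]])
    else stop("unknown reaction or tag: ", r)
  }, character(1))
  ids <- unique(ids)
  mean_a <- colMeans(ens_a$fluxes[, ids, drop = FALSE])
  mean_b <- colMeans(ens_b$fluxes[, ids, drop = FALSE])
  sd_a <- apply(ens_a$fluxes[, ids, drop = FALSE], 2, stats::sd)
  sd_b <- apply(ens_b$fluxes[, ids, drop = FALSE], 2, stats::sd)
  diff <- mean_a - mean_b
  data.frame(reaction = ids,
             mean_a = unname(mean_a), sd_a = unname(sd_a),
             mean_b = unname(mean_b), sd_b = unname(sd_b),
             difference = unname(diff),
             direction = ifelse(abs(diff) < 1e-12, "equal",
                                ifelse(diff > 0, "higher_in_a",
                                       "higher_in_b")),
             row.names = NULL, stringsAsFactors = FALSE)
}
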