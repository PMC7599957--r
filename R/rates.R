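## Rate-law evaluation.  A model+parameter pair is "compiled" once into
## index vectors so that the ODE right-hand side costs a handful of
## vectorised operations per call; the same structure carries analytic
## derivatives of every rate law for the Jacobian and elasticities.

.compileModel <- function(model, params) {
  sp <- model@species
  k <- getConstants(params)
  init <- initialConcentrations(params)
  spIdx <- setNames(seq_len(nrow(sp)), sp$id)
  dyn <- sp$id[sp$role == "dynamic"]
  bnd <- sp$id[sp$role == "boundary"]
  conc0 <- sp$initial_value
  names(conc0) <- sp$id
  conc0[names(init)[names(init) %in% sp$id]] <-
    init[names(init) %in% sp$id]

  pval <- function(ref, rid) {
    if (!ref %in% names(k))
      stop(sprintf("reaction %s references missing parameter '%s'", rid, ref))
    k[[ref]]
  }

  nr <- length(model@reactions)
  fo <- bi <- mm <- rev <- list()
  reg <- list(act = list())
  factors <- vector("list", nr)  # analytic factorisation per reaction
  for (j in seq_len(nr)) {
    r <- model@reactions[[j]]
    subs <- vapply(r$substrates, `[[`, character(1), "species")
    fl <- list()
    law <- r$rate_law
    if (law == "mass_action_1st_order") {
      kk <- pval(r$params$k, r$id)
      fo$rx <- c(fo$rx, j); fo$s <- c(fo$s, spIdx[[subs[1]]]); fo$k <- c(fo$k, kk)
      fl <- c(fl, list(list(type = "lin", s = spIdx[[subs[1]]], k = kk)))
    } else if (law == "mass_action_bimolecular") {
      kk <- pval(r$params$k, r$id)
      bi$rx <- c(bi$rx, j); bi$s1 <- c(bi$s1, spIdx[[subs[1]]])
      bi$s2 <- c(bi$s2, spIdx[[subs[2]]]); bi$k <- c(bi$k, kk)
      fl <- c(fl, list(list(type = "lin", s = spIdx[[subs[1]]], k = kk),
                       list(type = "lin", s = spIdx[[subs[2]]], k = 1)))
    } else if (law == "michaelis_menten_irreversible") {
      vm <- pval(r$params$vmax, r$id); km <- pval(r$params$km, r$id)
      mm$rx <- c(mm$rx, j); mm$s <- c(mm$s, spIdx[[subs[1]]])
      mm$vmax <- c(mm$vmax, vm); mm$km <- c(mm$km, km)
      fl <- c(fl, list(list(type = "mm", s = spIdx[[subs[1]]], vmax = vm, km = km)))
    } else if (law == "reversible_mass_action") {
      kf <- pval(r$params$kf, r$id); kr <- pval(r$params$kr, r$id)
      prods <- vapply(r$products, `[[`, character(1), "species")
      rev$rx <- c(rev$rx, j); rev$s1 <- c(rev$s1, spIdx[[subs[1]]])
      rev$s2 <- c(rev$s2, spIdx[[prods[1]]])
      rev$kf <- c(rev$kf, kf); rev$kr <- c(rev$kr, kr)
      fl <- c(fl, list(list(type = "rev", s1 = spIdx[[subs[1]]],
                            s2 = spIdx[[prods[1]]], kf = kf, kr = kr)))
    } else if (law == "regulated_synthesis") {
      basal <- pval(r$params$basal, r$id)
      acts <- Filter(function(m) m$mode == "activator", r$modifiers)
      reg$rx <- c(reg$rx, j); reg$s <- c(reg$s, spIdx[[subs[1]]])
      reg$basal <- c(reg$basal, basal)
      gs <- vapply(acts, function(m) pval(m$gain, r$id), numeric(1))
      as <- vapply(acts, function(m) spIdx[[m$species]], numeric(1))
      reg$act[[length(reg$rx)]] <- list(s = as, gain = gs)
      fl <- c(fl, list(list(type = "lin", s = spIdx[[subs[1]]], k = 1),
                       list(type = "regbase", s = as, gain = gs, basal = basal)))
    }
    ## multiplicative modifier factors (catalysts, and activators/inhibitors
    ## attached to non-regulated laws)
    for (m in r$modifiers) {
      if (m$mode == "catalyst" && !m$lumped) {
        fo2 <- spIdx[[m$species]]
        fl <- c(fl, list(list(type = "lin", s = fo2, k = 1)))
        reg$cat <- rbind(reg$cat, c(j, fo2))
      } else if (m$mode == "activator" && law != "regulated_synthesis") {
        g <- pval(m$gain, r$id)
        fl <- c(fl, list(list(type = "actf", s = spIdx[[m$species]], gain = g)))
        reg$actf <- rbind(reg$actf, c(j, spIdx[[m$species]], g))
      } else if (m$mode == "inhibitor") {
        ki <- pval(m$ki, r$id)
        fl <- c(fl, list(list(type = "inh", s = spIdx[[m$species]], ki = ki)))
        reg$inh <- rbind(reg$inh, c(j, spIdx[[m$species]], ki))
      }
    }
    factors[[j]] <- fl
  }

  list(spIds = sp$id, dynIds = dyn, bndIds = bnd,
       dynIdx = spIdx[dyn], conc0 = conc0,
       N = model@stoich, nr = nr,
       fo = fo, bi = bi, mm = mm, rev = rev, reg = reg,
       factors = factors,
       irrev = !vapply(model@reactions, function(r) isTRUE(r$reversible), logical(1)),
       rxIds = vapply(model@reactions, `[[`, character(1), "id"))
}

## reaction rates from a full concentration vector (model species order)
.ratesFromConc <- function(comp, conc) {
  v <- numeric(comp$nr)
  fo <- comp$fo; bi <- comp$bi; mm <- comp$mm; rv <- comp$rev; reg <- comp$reg
  if (length(fo$rx)) v[fo$rx] <- fo$k * conc[fo$s]
  if (length(bi$rx)) v[bi$rx] <- bi$k * conc[bi$s1] * conc[bi$s2]
  if (length(mm$rx)) {
    s <- conc[mm$s]
    v[mm$rx] <- mm$vmax * s / (mm$km + s)
  }
  if (length(rv$rx)) v[rv$rx] <- rv$kf * conc[rv$s1] - rv$kr * conc[rv$s2]
  if (length(reg$rx)) {
    for (i in seq_along(reg$rx)) {
      a <- reg$act[[i]]
      base <- reg$basal[i] + if (length(a$s)) sum(a$gain * conc[a$s]) else 0
      v[reg$rx[i]] <- conc[reg$s[i]] * base
    }
  }
  if (!is.null(reg$cat))
    for (i in seq_len(nrow(reg$cat)))
      v[reg$cat[i, 1]] <- v[reg$cat[i, 1]] * conc[reg$cat[i, 2]]
  if (!is.null(reg$actf))
    for (i in seq_len(nrow(reg$actf)))
      v[reg$actf[i, 1]] <- v[reg$actf[i, 1]] *
        (1 + reg$actf[i, 3] * conc[reg$actf[i, 2]])
  if (!is.null(reg$inh))
    for (i in seq_len(nrow(reg$inh))) {
      ki <- reg$inh[i, 3]
      v[reg$inh[i, 1]] <- v[reg$inh[i, 1]] * ki / (ki + conc[reg$inh[i, 2]])
    }
  v
}

.fullConc <- function(comp, state) {
  conc <- comp$conc0
  if (!is.null(names(state)) && !all(names(state) == comp$dynIds)) {
    missing <- setdiff(comp$dynIds, names(state))
    if (length(missing))
      stop(sprintf("state lacks dynamic species: %s", paste(missing, collapse = ", ")))
    state <- state[comp$dynIds]
  }
  if (length(state) != length(comp$dynIds))
    stop("state must have one entry per dynamic species")
  conc[comp$dynIdx] <- as.numeric(state)
  conc
}

## factor value and per-species derivative (for analytic Jacobian)
.factorEval <- function(f, conc) {
  switch(f$type,
    lin = list(val = f$k * conc[f$s], d = setNames(f$k, f$s)),
    mm = {
      s <- conc[f$s]
      list(val = f$vmax * s / (f$km + s),
           d = setNames(f$vmax * f$km / (f$km + s)^2, f$s))
    },
    rev = list(val = f$kf * conc[f$s1] - f$kr * conc[f$s2],
               d = setNames(c(f$kf, -f$kr), c(f$s1, f$s2))),
    regbase = {
      val <- f$basal + if (length(f$s)) sum(f$gain * conc[f$s]) else 0
      d <- if (length(f$s)) setNames(f$gain, f$s) else setNames(numeric(0), character(0))
      list(val = val, d = d)
    },
    actf = list(val = 1 + f$gain * conc[f$s], d = setNames(f$gain, f$s)),
    inh = {
      c0 <- conc[f$s]
      list(val = f$ki / (f$ki + c0), d = setNames(-f$ki / (f$ki + c0)^2, f$s))
    },
    stop("unknown factor type"))
}

## unscaled elasticities dv/dc for all species columns (full species set)
.unscaledElasticities <- function(comp, conc) {
  E <- matrix(0, comp$nr, length(comp$spIds))
  for (j in seq_len(comp$nr)) {
    fl <- lapply(comp$factors[[j]], .factorEval, conc = conc)
    vals <- vapply(fl, `[[`, numeric(1), "val")
    for (i in seq_along(fl)) {
      others <- prod(vals[-i])
      d <- fl[[i]]$d
      for (nm in names(d)) {
        s <- as.integer(nm)
        E[j, s] <- E[j, s] + d[[nm]] * others
      }
    }
  }
  E
}

.checkNonNegative <- function(comp, state, tol = 0) {
  bad <- which(as.numeric(state) < -abs(tol))
  if (length(bad))
    stop(sprintf("negative concentration for species %s",
                 paste(comp$dynIds[bad], collapse = ", ")))
}

#' Reaction rates at a given state
#'
#' Evaluates all rate laws at the supplied concentrations. Boundary species
#' are held at their constant pool values from \code{params}.
#'
#' @param model a [CholModel-class].
#' @param state numeric vector of dynamic-species concentrations, in model
#'   order or named by species id.
#' @param params a [ParameterSet-class].
#' @return named numeric vector of reaction rates (uMoles/min), one per
#'   reaction. Irreversible rates are non-negative for non-negative states;
#'   reversible rates carry the net sign.
#' @examples
#' f <- makeFixture("tiny_chain")
#' reactionRates(f$model, c(A = 1, B = 0.5, C = 0.1), f$params)
#' @export
reactionRates <- function(model, state, params) {
  comp <- .compileModel(model, params)
  .checkNonNegative(comp, if (is.null(names(state))) state else state[comp$dynIds])
  v <- .ratesFromConc(comp, .fullConc(comp, state))
  setNames(v, comp$rxIds)
}

#' ODE right-hand side
#'
#' Time derivative of the dynamic species: the stoichiometry matrix applied
#' to the reaction-rate vector. Boundary species have zero derivative by
#' construction (they are not part of the dynamic state).
#'
#' @inheritParams reactionRates
#' @return named numeric vector d(state)/dt over dynamic species.
#' @examples
#' f <- makeFixture("tiny_chain")
#' odeRHS(f$model, c(A = 1, B = 0.5, C = 0.1), f$params)
#' @export
odeRHS <- function(model, state, params) {
  comp <- .compileModel(model, params)
  .checkNonNegative(comp, if (is.null(names(state))) state else state[comp$dynIds])
  v <- .ratesFromConc(comp, .fullConc(comp, state))
  setNames(as.numeric(comp$N %*% v), comp$dynIds)
}
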