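# Macroscopic stepwise treatment of a cluster of interacting ionizable
# sites as a single polyprotic acid: species fractions and transition
# curves from a generalised Henderson-Hasselbalch model, summarisation of
# per-pH charge-state samples, least-squares pKa fitting with bootstrap
# intervals, and a multinomial simulator of constant-pH charge-state
# series.

#' Construct a polyprotic cluster model
#'
#' @param pka numeric vector of macroscopic stepwise pKa values, one per
#'   titratable site, non-decreasing
#' @param hill optional per-transition Hill coefficients (default 1)
#' @return a \linkS4class{PolyproticModel}
#' @examples
#' polyproticModel(c(4, 5.5, 6.8, 8, 9, 10))
#' @export
polyproticModel <- function(pka, hill = 1) {
  new("PolyproticModel", pka = as.numeric(pka),
      hill = rep_len(as.numeric(hill), length(pka)))
}

#' Species fractions of a polyprotic cluster versus pH
#'
#' The fraction of the j-fold deprotonated species is proportional to
#' 10^(sum_i<=j n_i (pH - pKa_i)), normalised so the fractions sum to one
#' at every pH (computed in log space for stability).
#'
#' @param model a \linkS4class{PolyproticModel}
#' @param pH numeric grid of pH values
#' @return matrix P with x+1 rows (charge states j = 0..x) and one column
#'   per pH value
#' @export
speciesFractions <- function(model, pH) {
  x <- length(model@pka)
  # log10 weights: row j+1 holds state j
  lw <- rbind(0, apply(outer(model@hill, pH) -
                         matrix(model@hill * model@pka, x, length(pH)),
                       2, cumsum))
  if (x == 1) lw <- rbind(0, matrix(lw[-1, ], 1))
  mx <- apply(lw, 2, max)
  w <- 10^sweep(lw, 2, mx)
  P <- sweep(w, 2, colSums(w), "/")
  rownames(P) <- as.character(0:x)
  colnames(P) <- as.character(pH)
  P
}

#' Per-transition titration curves
#'
#' Cumulative occupancy f_j(pH) = P(charge >= j), the probability that at
#' least j sites are deprotonated. Each f_j is monotone non-decreasing in
#' pH and crosses 0.5 at pKa_j when the transitions are well separated.
#'
#' @inheritParams speciesFractions
#' @return matrix with x rows (transitions j = 1..x) and one column per pH
#' @export
transitionCurves <- function(model, pH) {
  P <- speciesFractions(model, pH)
  x <- length(model@pka)
  f <- apply(P, 2, function(col) rev(cumsum(rev(col))))[-1, , drop = FALSE]
  rownames(f) <- as.character(seq_len(x))
  f
}

#' Summarise an observed charge-state series
#'
#' Per-pH observed fractions with multinomial standard errors.
#'
#' @param series a \linkS4class{ChargeStateSeries}
#' @return list with \code{p} (fractions, states x pH), \code{se}
#'   (standard errors, same shape) and \code{n} (samples per pH)
#' @export
summarizeStates <- function(series) {
  counts <- series@counts
  n <- rowSums(counts)
  if (any(n == 0)) stop("pH value with no samples: ",
                        paste(series@pH[n == 0], collapse = ", "))
  p <- counts / n
  se <- sqrt(p * (1 - p) / n)
  states <- as.character(seq_len(ncol(counts)) - 1)
  p <- t(p); se <- t(se)
  dimnames(p) <- dimnames(se) <- list(states, as.character(series@pH))
  list(p = p, se = se, n = n)
}

#' Simulate a constant-pH charge-state series
#'
#' Draws per-pH samples of the cluster charge state from the model's
#' species fractions: i.i.d. multinomial draws by default, or an
#' autocorrelated chain (with probability \code{rho} the previous state is
#' kept, otherwise a fresh draw is taken) emulating the autocorrelation of
#' molecular-dynamics protonation-state series while preserving the
#' marginal fractions.
#'
#' @param model a \linkS4class{PolyproticModel}
#' @param pH numeric grid of pH values
#' @param n samples per pH value
#' @param seed integer seed (required; the only source of randomness)
#' @param rho AR(1)-style stickiness in [0, 1), default 0 (i.i.d.)
#' @return a \linkS4class{ChargeStateSeries}
#' @export
simulateChargeSeries <- function(model, pH, n, seed, rho = 0) {
  stopifnot(n >= 1, rho >= 0, rho < 1)
  x <- length(model@pka)
  P <- speciesFractions(model, pH)
  counts <- matrix(0L, length(pH), x + 1,
                   dimnames = list(NULL, as.character(0:x)))
  rs <- .seededRNG(seed)
  for (i in seq_along(pH)) {
    probs <- P[, i]
    if (rho == 0) {
      counts[i, ] <- as.integer(rs$multinom(n, probs))
    } else {
      states <- integer(n)
      states[1] <- rs$sample(x + 1, probs)
      for (t in 2:n) {
        states[t] <- if (rs$unif() < rho) states[t - 1] else
          rs$sample(x + 1, probs)
      }
      tab <- tabulate(states, nbins = x + 1)
      counts[i, ] <- as.integer(tab)
    }
  }
  new("ChargeStateSeries", pH = pH, counts = counts,
      meta = list(seed = seed, rho = rho))
}

# Local RNG wrapper: isolates the package's draws from the global stream.
.seededRNG <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, globalenv())
    s
  })
  withState <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    res <- f()
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, globalenv())
    res
  }
  list(
    multinom = function(n, probs) withState(function()
      stats::rmultinom(1, n, probs)[, 1]),
    sample = function(k, probs) withState(function()
      sample.int(k, 1, prob = probs)),
    unif = function() withState(function() stats::runif(1))
  )
}

# Ordered-pKa parameterisation: theta = (pka1, log(diff2), ..., log(diffx)).
.thetaToPka <- function(theta) {
  if (length(theta) == 1) return(theta)
  cumsum(c(theta[1], exp(theta[-1])))
}
.pkaToTheta <- function(pka) {
  if (length(pka) == 1) return(pka)
  d <- pmax(diff(pka), 1e-3)
  c(pka[1], log(d))
}

# Sum-of-squares objective between model species fractions and observed.
.titrationSS <- function(theta, pObs, pH, hill) {
  pka <- .thetaToPka(theta)
  model <- new("PolyproticModel", pka = pka,
               hill = rep_len(hill, length(pka)))
  P <- speciesFractions(model, pH)
  sum((P - pObs)^2)
}

#' Fit macroscopic stepwise pKa values
#'
#' Least-squares fit of the generalised Henderson-Hasselbalch species
#' fractions to observed per-pH charge-state fractions, over an ordered
#' pKa vector (ordering enforced through a log-difference
#' parameterisation). Initial values come from the pH at which the mean
#' charge crosses j - 1/2, with additional spread-out multi-starts;
#' optional bootstrap intervals resample the per-pH counts. Transitions
#' whose fitted midpoints fall outside the pH grid are flagged as
#' unidentifiable.
#'
#' @param observed a \linkS4class{ChargeStateSeries}, or a fraction matrix
#'   (states x pH) as returned by \code{summarizeStates()$p} (then
#'   \code{nPerPH} supplies bootstrap sample sizes)
#' @param x number of titratable sites
#' @param pH numeric grid matching the observations (taken from the
#'   series when omitted)
#' @param hill Hill coefficients, fixed during the fit (default 1)
#' @param nBoot bootstrap resamples for intervals (default 200; 0 skips)
#' @param seed seed for the bootstrap resampling
#' @param nPerPH samples per pH when \code{observed} is a plain matrix
#' @return a \linkS4class{TitrationFit}
#' @export
fitMacroscopicPkas <- function(observed, x, pH = NULL, hill = 1,
                               nBoot = 200, seed = 1, nPerPH = NULL) {
  if (is(observed, "ChargeStateSeries")) {
    if (is.null(pH)) pH <- observed@pH
    summ <- summarizeStates(observed)
    pObs <- summ$p
    nPerPH <- summ$n
  } else {
    pObs <- observed
    if (is.null(pH)) stop("pH grid required with a plain fraction matrix")
  }
  if (nrow(pObs) != x + 1) stop("observed must have x+1 charge states")
  fit <- .fitOnce(pObs, pH, x, hill)
  pka <- fit$pka
  # identifiability: a transition is informed only if its midpoint lies
  # inside the pH grid
  ident <- pka >= min(pH) & pka <= max(pH)
  ci <- matrix(numeric(0), 0, 0)
  if (nBoot > 0 && !is.null(nPerPH)) {
    rs <- .seededRNG(seed)
    boot <- matrix(NA_real_, nBoot, x)
    for (b in seq_len(nBoot)) {
      pb <- vapply(seq_along(pH), function(i)
        rs$multinom(nPerPH[i], pObs[, i]) / nPerPH[i], numeric(x + 1))
      fb <- .fitOnce(pb, pH, x, hill, init = fit$pka, fast = TRUE)
      boot[b, ] <- fb$pka
    }
    ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975))
  }
  new("TitrationFit", pka = pka, hill = rep_len(hill, x), ci = ci,
      rss = fit$rss, converged = fit$converged,
      identifiable = all(ident))
}

# One multi-start Nelder-Mead/BFGS fit. fast = TRUE (bootstrap refits)
# runs a single BFGS start from the supplied initial values.
.fitOnce <- function(pObs, pH, x, hill, init = NULL, fast = FALSE) {
  if (fast && !is.null(init)) {
    opt <- stats::optim(.pkaToTheta(init), .titrationSS, pObs = pObs,
                        pH = pH, hill = hill, method = "BFGS",
                        control = list(maxit = 200, reltol = 1e-10))
    return(list(pka = .thetaToPka(opt$par), rss = opt$value,
                converged = opt$convergence == 0))
  }
  starts <- list()
  if (!is.null(init)) starts[[1]] <- init
  # crossing-based start: pH where the mean charge passes j - 1/2
  meanQ <- as.numeric(colSums(pObs * (0:x)))
  cross <- vapply(seq_len(x), function(j) {
    above <- which(meanQ >= j - 0.5)
    if (length(above) == 0) return(max(pH) + 2 * j / x)
    i <- min(above)
    if (i == 1) return(min(pH) - 2 * (x - j + 1) / x)
    # linear interpolation
    pH[i - 1] + (j - 0.5 - meanQ[i - 1]) / (meanQ[i] - meanQ[i - 1]) *
      (pH[i] - pH[i - 1])
  }, numeric(1))
  starts[[length(starts) + 1]] <- sort(cross)
  starts[[length(starts) + 1]] <- seq(min(pH), max(pH), length.out = x)
  starts[[length(starts) + 1]] <- seq(min(pH) - 1, max(pH) + 1,
                                      length.out = x)
  if (x == 1) {
    opt <- stats::optimize(.titrationSS, c(min(pH) - 6, max(pH) + 6),
                           pObs = pObs, pH = pH, hill = hill,
                           tol = 1e-10)
    return(list(pka = opt$minimum, rss = opt$objective, converged = TRUE))
  }
  best <- NULL
  for (s in starts) {
    theta0 <- .pkaToTheta(sort(s))
    opt <- try(stats::optim(theta0, .titrationSS, pObs = pObs, pH = pH,
                            hill = hill, method = "Nelder-Mead",
                            control = list(maxit = 2000 + 500 * x,
                                           reltol = 1e-12)), silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all optimisation starts failed")
  # polish
  opt <- try(stats::optim(best$par, .titrationSS, pObs = pObs, pH = pH,
                          hill = hill, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-14)),
             silent = TRUE)
  if (!inherits(opt, "try-error") && opt$value <= best$value) best <- opt
  list(pka = .thetaToPka(best$par), rss = best$value,
       converged = best$convergence == 0)
}
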