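#' Prior specification for the Poisson-lognormal mixed model
#'
#' Variance components take scalar inverse-Wishart priors,
#' parameterised by a scale `V` and degree of belief `nu` (equivalent
#' to an inverse-gamma with shape `nu/2` and rate `nu * V / 2`). The
#' non-informative choice `nu = 0` is improper; it is clamped to a
#' small positive floor so the posterior is proper, and results are
#' insensitive to the floor. The residual (log-scale overdispersion)
#' prior is a `d`-dimensional inverse-Wishart across the modelled
#' units (`d` = OTUs including the sum-OTU) with scale `V * I` and
#' `nu = d - 0.998`, supplied automatically when `nu = NULL`. Its
#' marginal on each unit's variance is inverse-gamma with shape
#' `(nu - d + 1)/2 = 0.001` and rate `V/2` — near non-informative per
#' OTU; the `-0.998` exists precisely so the marginal degree of
#' freedom is 0.002.
#'
#' @param fixed_effect_variance Gaussian prior variance for
#'   intercepts and fixed effects; default `1e8` (over-dispersed,
#'   effectively flat).
#' @param coverage `list(V, nu)` for the coverage-effect variance.
#' @param group `list(V, nu)` for each random-group variance.
#' @param residual `list(V, nu)`; `nu = NULL` means
#'   `n_units - 0.998`.
#' @param nu_floor Lower clamp applied to `nu` of the coverage and
#'   group priors; default 0.002.
#' @return A list of class `"pln_priors"`.
#' @export
pln_priors <- function(fixed_effect_variance = 1e8,
                       coverage = list(V = 1, nu = 0),
                       group = list(V = 1, nu = 0),
                       residual = list(V = 1, nu = NULL),
                       nu_floor = 0.002) {
  stopifnot(fixed_effect_variance > 0, coverage$V > 0, group$V > 0,
            residual$V > 0, nu_floor > 0)
  coverage$nu <- max(coverage$nu, nu_floor)
  group$nu <- max(group$nu, nu_floor)
  structure(list(fixed_effect_variance = fixed_effect_variance,
                 coverage = coverage, group = group,
                 residual = residual, nu_floor = nu_floor),
            class = "pln_priors")
}

# scalar inverse-Wishart(V, nu) == inverse-gamma(shape nu/2, rate nu*V/2)
.rinvgamma1 <- function(shape, rate) 1 / rgamma(1L, shape = shape, rate = rate)

.dinvgamma_log <- function(x, shape, rate)
  shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x

#' Fit the Poisson-lognormal mixed model by MCMC
#'
#' The observation model is `y ~ Poisson(exp(eta))` with latent
#' log-rate `eta ~ Normal(psi, sigma2_o)`, where for OTU `o` in
#' condition cell `i`, sample `k`, group `j`:
#' `psi = I_o + B_oi + c_k + a_oj`. `I_o` is an OTU intercept, `B_oi`
#' the OTU-specific fixed effect of the condition cell, `c_k` a
#' coverage random effect shared across OTUs within a sample, and
#' `a_oj` an optional OTU-specific group random effect. The residual
#' log-variance `sigma2_o` is OTU-specific. An artificial sum-OTU
#' carrying each sample's total is fitted jointly (see
#' [build_design()]); effects are later reported relative to it.
#'
#' Sampling is Metropolis-within-Gibbs: adaptive random-walk updates
#' for the latent log-rates, conjugate Gaussian updates for all
#' location effects, and conjugate scalar inverse-Wishart updates for
#' variance components. The coverage effects are recentred to mean
#' zero each sweep (the mean is absorbed into the intercepts), which
#' resolves the translation ridge between `c_k` and the intercepts.
#'
#' @inheritParams build_design
#' @param iterations,burn_in,thin MCMC length controls; retained
#'   draws number `(iterations - burn_in) / thin`. Defaults
#'   55000/5000/50, chosen to give effective sizes above ~200 on
#'   datasets of the scale this model targets (up to ~200 OTUs).
#' @param seed Integer RNG seed; identical seeds give bit-identical
#'   chains.
#' @param priors A [pln_priors()] object.
#' @param include_coverage Model the per-sample coverage effect
#'   `c_k`? Default `TRUE`; disable only for reduced calibration
#'   models.
#' @param sigma2_fixed Optional fixed residual log-variance (single
#'   value or per-unit vector); when supplied the residual variances
#'   are not sampled. Intended for calibration studies against
#'   closed-form posteriors.
#' @param verbose Print progress every 1000 sweeps?
#' @return An object of class `"pln_fit"`: `draws` (matrix, one row
#'   per retained draw, named columns `I[otu]`, `B[otu:coef]`,
#'   `c[sample]`, `var_c`, `a[factor:otu:level]`,
#'   `var_a[factor:otu]`, `sigma2[otu]`), `design`, `otus`, `ess`
#'   (effective sample sizes for intercepts and fixed effects),
#'   `accept_rate`, and the call settings.
#' @export
pln_fit <- function(data, fixed = NULL, random = NULL,
                    interactions = TRUE, iterations = 55000,
                    burn_in = 5000, thin = 50, seed = 1L,
                    priors = pln_priors(), sum_otu = TRUE,
                    include_coverage = TRUE, sigma2_fixed = NULL,
                    verbose = FALSE) {
  if (inherits(data, "pln_design")) design <- data
  else design <- build_design(data, fixed = fixed, random = random,
                              interactions = interactions,
                              sum_otu = sum_otu)
  stopifnot(iterations > burn_in, thin >= 1)
  if (!inherits(priors, "pln_priors")) priors <- do.call(pln_priors, priors)
  set.seed(as.integer(seed))

  long <- design$long
  otus <- design$otus
  U <- length(otus); K <- length(design$samples)
  C <- length(design$cells)
  Xc <- design$X_cell; p <- ncol(Xc)
  y <- long$count
  oi <- match(long$otu, otus)
  ki <- match(long$sample, design$samples)
  ci <- match(long$cell, design$cells)
  N <- length(y)

  cell_n <- tabulate(match(design$sample_cell, design$cells), nbins = C)
  if (any(cell_n < 2L))
    warn(paste0("Condition cell(s) with fewer than 2 samples: ",
                paste(design$cells[cell_n < 2L], collapse = ", ")))

  nu_r <- priors$residual$nu
  if (is.null(nu_r)) nu_r <- U - 0.998
  V_r <- priors$residual$V
  # the residual prior is a U-dimensional inverse-Wishart (scale V*I,
  # df nu_r); its marginal on each OTU's variance is inverse-gamma
  # with shape (nu_r - U + 1)/2 and rate V/2 -- with the default
  # nu_r = U - 0.998 that is shape 0.001: near non-informative per OTU
  res_shape0 <- (nu_r - U + 1) / 2
  res_rate0 <- V_r / 2
  if (res_shape0 <= 0)
    abort("Residual prior nu too small: need nu > n_units - 1.")
  fev <- priors$fixed_effect_variance

  fix_s2 <- !is.null(sigma2_fixed)
  sig2 <- if (fix_s2) rep_len(sigma2_fixed, U) else rep(1, U)

  # initial values
  eta <- log(y + 0.5)
  I <- vapply(seq_len(U), function(o) mean(eta[oi == o]), numeric(1))
  B <- matrix(0, U, p)
  cc <- rep(0, K)
  var_c <- 1
  rf <- design$random
  nrf <- length(rf)
  A <- list(); var_a <- list(); gi <- list(); Lr <- integer(0)
  if (nrf) {
    for (r in seq_len(nrf)) {
      Lr[r] <- length(rf[[r]]$levels)
      A[[r]] <- matrix(0, U, Lr[r])
      var_a[[r]] <- rep(1, U)
      gi[[r]] <- rf[[r]]$index[ki]   # level index per observation
    }
  }

  # constant pieces for the conjugate location updates
  Zc <- cbind(`(I)` = 1, Xc)                       # C x (p+1)
  ZtZ <- crossprod(Zc * sqrt(cell_n))              # common across OTUs
  Dprior <- diag(1 / fev, p + 1L)
  grp_oc <- (oi - 1L) * C + ci                     # per-obs (otu, cell) bin
  obs_per_samp_prec <- function() sum(1 / sig2)    # complete design

  step <- rep(0.5, N)
  acc_batch <- rep(0, N); batch_n <- 0L; batch_no <- 0L
  n_keep <- (iterations - burn_in) %/% thin

  # per-bin count sums for the joint translation moves (constant)
  Sy_oc <- rowsum(y, grp_oc)
  Sy_oc <- matrix(Sy_oc[match(seq_len(U * C),
                              as.integer(rownames(Sy_oc))), ],
                  U, C, byrow = TRUE)
  Sy_o <- rowSums(Sy_oc)
  Sy_k <- as.vector(rowsum(y, ki)[as.character(seq_len(K)), ])
  x_binary <- p > 0 && all(Xc %in% c(0, 1))
  tA <- rep(0.1, U); tB <- matrix(0.1, U, max(p, 1L)); tC <- rep(0.1, K)
  aA <- rep(0, U); aB <- matrix(0, U, max(p, 1L)); aC <- rep(0, K)

  a_names <- character(0)
  if (nrf) for (r in seq_len(nrf))
    a_names <- c(a_names,
                 paste0("a[", names(rf)[r], ":",
                        rep(otus, each = Lr[r]), ":",
                        rep(rf[[r]]$levels, times = U), "]"),
                 paste0("var_a[", names(rf)[r], ":", otus, "]"))
  par_names <- c(paste0("I[", otus, "]"),
                 if (p) paste0("B[", rep(otus, each = p), ":",
                               rep(colnames(Xc), times = U), "]"),
                 if (include_coverage) c(paste0("c[", design$samples, "]"),
                                         "var_c"),
                 a_names,
                 paste0("sigma2[", otus, "]"))
  draws <- matrix(NA_real_, n_keep, length(par_names),
                  dimnames = list(NULL, par_names))
  acc_total <- 0; acc_n <- 0
  keep_i <- 0L

  a_contrib <- function() {
    out <- rep(0, N)
    if (nrf) for (r in seq_len(nrf)) out <- out + A[[r]][cbind(oi, gi[[r]])]
    out
  }
  XB_obs <- function() {
    if (p == 0L) return(rep(0, N))
    (B %*% t(Xc))[cbind(oi, ci)]
  }

  for (it in seq_len(iterations)) {
    acont <- a_contrib()
    psi <- I[oi] + XB_obs() + cc[ki] + acont
    s2o <- sig2[oi]

    ## latent log-rates: vectorised random-walk Metropolis
    prop <- eta + step * rnorm(N)
    logr <- y * (prop - eta) - (exp(prop) - exp(eta)) -
      ((prop - psi)^2 - (eta - psi)^2) / (2 * s2o)
    acc <- log(runif(N)) < logr
    eta[acc] <- prop[acc]
    if (it <= burn_in) {
      acc_batch <- acc_batch + acc; batch_n <- batch_n + 1L
      if (batch_n == 50L) {
        batch_no <- batch_no + 1L
        gain <- min(0.25, 1 / sqrt(batch_no))
        step <- step * exp((acc_batch / 50 - 0.44) * gain)
        acc_batch[] <- 0; batch_n <- 0L
      }
    } else { acc_total <- acc_total + sum(acc); acc_n <- acc_n + N }

    ## intercept + fixed effects, jointly per OTU (conjugate)
    r1 <- eta - cc[ki] - acont
    S <- rowsum(r1, grp_oc)           # (U*C) x 1, bins sorted
    S <- matrix(S[match(seq_len(U * C), as.integer(rownames(S))), ],
                U, C, byrow = TRUE)
    for (o in seq_len(U)) {
      prec <- ZtZ / sig2[o] + Dprior
      b <- crossprod(Zc, S[o, ]) / sig2[o]
      ch <- chol(prec)
      mu <- backsolve(ch, forwardsolve(t(ch), b))
      th <- mu + backsolve(ch, rnorm(p + 1L))
      I[o] <- th[1L]
      if (p) B[o, ] <- th[-1L]
    }

    ## coverage effects (conjugate), recentred
    if (include_coverage) {
      r2 <- eta - I[oi] - XB_obs() - acont
      num <- rowsum(r2 / s2o, ki)
      num <- num[match(seq_len(K), as.integer(rownames(num))), ]
      prec_k <- obs_per_samp_prec() + 1 / var_c
      cc <- num / prec_k + rnorm(K) / sqrt(prec_k)
      mshift <- mean(cc)
      cc <- cc - mshift
      I <- I + mshift
      var_c <- .rinvgamma1((priors$coverage$nu + K) / 2,
                           (priors$coverage$nu * priors$coverage$V +
                              sum(cc^2)) / 2)
    }

    ## group random effects (conjugate)
    if (nrf) {
      base <- I[oi] + XB_obs() + cc[ki]
      for (r in seq_len(nrf)) {
        other <- a_contrib() - A[[r]][cbind(oi, gi[[r]])]
        r3 <- eta - base - other
        bin <- (oi - 1L) * Lr[r] + gi[[r]]
        sums <- rowsum(r3, bin)
        sums <- matrix(sums[match(seq_len(U * Lr[r]),
                                  as.integer(rownames(sums))), ],
                       U, Lr[r], byrow = TRUE)
        cnt <- rowsum(rep(1, N), bin)
        cnt <- matrix(cnt[match(seq_len(U * Lr[r]),
                                as.integer(rownames(cnt))), ],
                      U, Lr[r], byrow = TRUE)
        cnt[is.na(cnt)] <- 0; sums[is.na(sums)] <- 0
        prec <- cnt / sig2 + 1 / var_a[[r]]
        A[[r]] <- (sums / sig2) / prec +
          matrix(rnorm(U * Lr[r]), U, Lr[r]) / sqrt(prec)
        ssq <- rowSums(A[[r]]^2)
        for (o in seq_len(U))
          var_a[[r]][o] <- .rinvgamma1(
            (priors$group$nu + Lr[r]) / 2,
            (priors$group$nu * priors$group$V + ssq[o]) / 2)
      }
    }

    ## joint translation moves: shift one location parameter together
    ## with the latent log-rates it feeds, jumping along the ridge
    ## between a location effect and the mean of its latent residuals
    ## (the Gibbs steps above move across the ridge only slowly when
    ## counts are large and sigma2 small)
    ee <- exp(eta)
    Se_oc <- rowsum(ee, grp_oc)
    Se_oc <- matrix(Se_oc[match(seq_len(U * C),
                                as.integer(rownames(Se_oc))), ],
                    U, C, byrow = TRUE)
    # (a) per-OTU intercept shifts
    dA <- tA * rnorm(U)
    lrA <- Sy_o * dA - (exp(dA) - 1) * rowSums(Se_oc) +
      dnorm(I + dA, 0, sqrt(fev), log = TRUE) -
      dnorm(I, 0, sqrt(fev), log = TRUE)
    okA <- log(runif(U)) < lrA
    if (any(okA)) {
      I[okA] <- I[okA] + dA[okA]
      shift <- ifelse(okA, dA, 0)
      eta <- eta + shift[oi]
      ee <- exp(eta)
    }
    # (b) per-coefficient fixed-effect shifts (binary design columns)
    if (x_binary) {
      Se_oc <- rowsum(ee, grp_oc)
      Se_oc <- matrix(Se_oc[match(seq_len(U * C),
                                  as.integer(rownames(Se_oc))), ],
                      U, C, byrow = TRUE)
      SyB <- Sy_oc %*% Xc
      SeB <- Se_oc %*% Xc
      dB <- tB[, seq_len(p), drop = FALSE] * matrix(rnorm(U * p), U, p)
      lrB <- SyB * dB - (exp(dB) - 1) * SeB +
        dnorm(B + dB, 0, sqrt(fev), log = TRUE) -
        dnorm(B, 0, sqrt(fev), log = TRUE)
      okB <- matrix(log(runif(U * p)), U, p) < lrB
      if (any(okB)) {
        shiftB <- ifelse(okB, dB, 0)
        B <- B + shiftB
        eta <- eta + (shiftB %*% t(Xc))[cbind(oi, ci)]
        ee <- exp(eta)
      }
    } else okB <- NULL
    # (c) per-sample coverage shifts
    if (include_coverage) {
      Se_k <- as.vector(rowsum(ee, ki)[as.character(seq_len(K)), ])
      dC <- tC * rnorm(K)
      lrC <- Sy_k * dC - (exp(dC) - 1) * Se_k +
        dnorm(cc + dC, 0, sqrt(var_c), log = TRUE) -
        dnorm(cc, 0, sqrt(var_c), log = TRUE)
      okC <- log(runif(K)) < lrC
      if (any(okC)) {
        cc[okC] <- cc[okC] + dC[okC]
        shiftC <- ifelse(okC, dC, 0)
        eta <- eta + shiftC[ki]
        # restore the mean-zero identifiability constraint
        mshift <- mean(cc)
        cc <- cc - mshift
        I <- I + mshift
      }
    } else okC <- NULL
    if (it <= burn_in) {
      aA <- aA + okA
      if (x_binary) aB[, seq_len(p)] <- aB[, seq_len(p)] + okB
      if (include_coverage) aC <- aC + okC
      if (batch_n == 0L) {  # batch boundary reached in the eta block
        gain <- min(0.25, 1 / sqrt(max(batch_no, 1L)))
        tA <- tA * exp((aA / 50 - 0.44) * gain); aA[] <- 0
        if (x_binary) {
          tB <- tB * exp((aB / 50 - 0.44) * gain); aB[] <- 0
        }
        if (include_coverage) {
          tC <- tC * exp((aC / 50 - 0.44) * gain); aC[] <- 0
        }
      }
    }

    ## residual log-variances
    if (!fix_s2) {
      eps <- eta - (I[oi] + XB_obs() + cc[ki] + a_contrib())
      ssq <- rowsum(eps^2, oi)
      ssq <- ssq[match(seq_len(U), as.integer(rownames(ssq))), ]
      m_o <- tabulate(oi, nbins = U)
      for (o in seq_len(U))
        sig2[o] <- .rinvgamma1(res_shape0 + m_o[o] / 2,
                               res_rate0 + ssq[o] / 2)
    }

    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      keep_i <- keep_i + 1L
      row <- c(I,
               if (p) as.vector(t(B)),
               if (include_coverage) c(cc, var_c),
               if (nrf) unlist(lapply(seq_len(nrf), function(r)
                 c(as.vector(t(A[[r]])), var_a[[r]]))),
               sig2)
      draws[keep_i, ] <- row
    }
    if (verbose && it %% 1000L == 0L)
      message("sweep ", it, "/", iterations)
  }

  ib_cols <- c(paste0("I[", otus, "]"),
               if (p) paste0("B[", rep(otus, each = p), ":",
                             rep(colnames(Xc), times = U), "]"))
  ess <- vapply(ib_cols, function(cn) {
    x <- draws[, cn]
    if (sd(x) == 0) return(NA_real_)
    as.numeric(coda::effectiveSize(x))
  }, numeric(1))
  if (any(!is.na(ess) & ess < 100))
    warn(paste0("Low effective sample size (< 100) for: ",
                paste(names(ess)[!is.na(ess) & ess < 100], collapse = ", "),
                ". Consider longer chains."))

  structure(list(draws = draws, design = design, otus = otus,
                 cells = design$cells, ref_cell = design$ref_cell,
                 X_cell = Xc, ess = ess,
                 accept_rate = if (acc_n) acc_total / acc_n else NA_real_,
                 settings = list(iterations = iterations,
                                 burn_in = burn_in, thin = thin,
                                 seed = as.integer(seed),
                                 include_coverage = include_coverage,
                                 sigma2_fixed = sigma2_fixed),
                 priors = priors),
            class = "pln_fit")
}

#' @export
print.pln_fit <- function(x, ...) {
  cat("Poisson-lognormal mixed model fit\n")
  cat("  units: ", length(x$otus), " (incl. sum-OTU: ",
      x$design$sum_otu, ")\n", sep = "")
  cat("  condition cells: ", paste(x$cells, collapse = ", "),
      " (reference: ", x$ref_cell, ")\n", sep = "")
  cat("  retained draws: ", nrow(x$draws), " (iterations ",
      x$settings$iterations, ", burn-in ", x$settings$burn_in,
      ", thin ", x$settings$thin, ", seed ", x$settings$seed, ")\n",
      sep = "")
  cat("  latent acceptance rate: ",
      round(x$accept_rate, 3), "\n", sep = "")
  cat("  min effective sample size (I, B): ",
      round(min(x$ess, na.rm = TRUE)), "\n", sep = "")
  invisible(x)
}

#' Joint log posterior density of a model state
#'
#' Evaluates the unnormalised log posterior targeted by [pln_fit()]
#' at a fully specified state, for diagnostics and validation. The
#' state carries the latent log-rates explicitly.
#'
#' @param state A list with elements `eta` (latent log-rates, one per
#'   long-format observation), `I`, `B` (matrix units x coefficients,
#'   may have 0 columns), `c` (per-sample coverage effects; omit or
#'   `NULL` if the model has none), `var_c`, `a`/`var_a` (lists per
#'   random factor), `sigma2` (per-unit residual log-variances).
#' @param design A [build_design()] result.
#' @param priors A [pln_priors()] object.
#' @return The joint log density (numeric scalar).
#' @export
pln_log_posterior <- function(state, design, priors = pln_priors()) {
  long <- design$long
  otus <- design$otus
  U <- length(otus)
  y <- long$count
  oi <- match(long$otu, otus)
  ki <- match(long$sample, design$samples)
  ci <- match(long$cell, design$cells)
  Xc <- design$X_cell; p <- ncol(Xc)
  eta <- state$eta
  if (any(!is.finite(eta))) abort("Nonfinite latent log-rate in state.")
  B <- state$B
  if (is.null(B)) B <- matrix(0, U, p)
  sig2 <- rep_len(state$sigma2, U)
  if (any(sig2 <= 0)) abort("Residual variances must be > 0.")
  psi <- state$I[oi] +
    (if (p) (B %*% t(Xc))[cbind(oi, ci)] else 0) +
    (if (!is.null(state$c)) state$c[ki] else 0)
  if (!is.null(design$random)) {
    for (r in seq_along(design$random))
      psi <- psi + state$a[[r]][cbind(oi, design$random[[r]]$index[ki])]
  }
  lp <- sum(y * eta - exp(eta) - lgamma(y + 1)) +
    sum(dnorm(eta, psi, sqrt(sig2[oi]), log = TRUE)) +
    sum(dnorm(c(state$I, if (p) B), 0,
              sqrt(priors$fixed_effect_variance), log = TRUE))
  nu_r <- priors$residual$nu
  if (is.null(nu_r)) nu_r <- U - 0.998
  # marginal of the U-dimensional inverse-Wishart residual prior
  lp <- lp + sum(.dinvgamma_log(sig2, (nu_r - U + 1) / 2,
                                priors$residual$V / 2))
  if (!is.null(state$c)) {
    lp <- lp + sum(dnorm(state$c, 0, sqrt(state$var_c), log = TRUE)) +
      .dinvgamma_log(state$var_c, priors$coverage$nu / 2,
                     priors$coverage$nu * priors$coverage$V / 2)
  }
  if (!is.null(design$random)) {
    for (r in seq_along(design$random)) {
      va <- rep_len(state$var_a[[r]], U)
      lp <- lp + sum(dnorm(state$a[[r]], 0,
                           sqrt(va[row(state$a[[r]])]), log = TRUE)) +
        sum(.dinvgamma_log(va, priors$group$nu / 2,
                           priors$group$nu * priors$group$V / 2))
    }
  }
  lp
}
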