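#' Connectivity of a focal male
#'
#' Metapopulation-style connectivity transplanted to males: the degree to
#' which a focal male is surrounded by competitors,
#' \deqn{C_i = \sum_{j \ne i} e^{-d_{ij}/\lambda_C},}
#' summing a negative-exponential decay of the pairwise distance over all
#' other males simultaneously present in the site, and optionally over
#' playback-station midpoints treated as additional competitors. Because
#' choice probabilities depend only on relative connectivities within a
#' choice situation, the overall elevation caused by adding males cancels
#' out downstream.
#'
#' The decay constant defaults to 200 m, matching the playback-proximity
#' covariate's e-folding distance; \code{decay = 1} reproduces the bare
#' formula \eqn{\sum e^{-d_{ij}}} with d in metres.
#'
#' @param focal length-2 numeric, the focal male's (x, y) in metres.
#' @param others two-column matrix or data frame of other males' (x, y);
#'   may have zero rows.
#' @param playbacks optional two-column matrix or data frame of playback
#'   midpoints to include as competitors (ignored when \code{NULL}).
#' @param decay e-folding distance \eqn{\lambda_C} in metres.
#' @return Non-negative scalar; 0 when there are no competitors at all.
#' @export
connectivity <- function(focal, others, playbacks = NULL, decay = 200) {
  stopifnot(length(focal) == 2, decay > 0)
  pts <- rbind(as_xy(others), as_xy(playbacks))
  if (is.null(pts) || nrow(pts) == 0) return(0)
  d <- sqrt((pts[, 1] - focal[1])^2 + (pts[, 2] - focal[2])^2)
  sum(exp(-d / decay))
}

as_xy <- function(p) {
  if (is.null(p)) return(NULL)
  p <- if (is.data.frame(p)) {
    cols <- if (all(c("x", "y") %in% names(p))) c("x", "y") else 1:2
    as.matrix(p[, cols])
  } else {
    matrix(p, ncol = 2)
  }
  storage.mode(p) <- "double"
  p
}

#' Connectivity of every male in a site snapshot
#'
#' @param males data frame with columns \code{x}, \code{y} (one row per
#'   male present in the site).
#' @param playbacks optional playback midpoints (columns \code{x},
#'   \code{y}).
#' @param include_playbacks whether playback midpoints count as
#'   competitors. They only ever contribute to real males' connectivity;
#'   they are never candidates themselves.
#' @param decay e-folding distance in metres.
#' @return Numeric vector of connectivities, one per male.
#' @export
compute_connectivities <- function(males, playbacks = NULL,
                                   include_playbacks = TRUE, decay = 200) {
  xy <- as_xy(males)
  n <- nrow(xy)
  pb <- if (include_playbacks) as_xy(playbacks) else NULL
  vapply(seq_len(n), function(i)
    connectivity(xy[i, ], xy[-i, , drop = FALSE], pb, decay),
    numeric(1))
}

#' One female settlement choice
#'
#' A choice event holds the snapshot of candidate males available to one
#' female at her decision date, each with habitat value H (attractiveness
#' raster at his territory centre, strictly positive) and connectivity C,
#' plus the index of the male she actually chose.
#'
#' @param candidates data frame with columns \code{male_id}, \code{x},
#'   \code{y}, \code{H}, \code{C}.
#' @param chosen integer index into \code{candidates}.
#' @param female_id,site,decision_date metadata.
#' @return Object of class \code{"choice_event"}.
#' @export
choice_event <- function(candidates, chosen, female_id = NA, site = NA,
                         decision_date = NA) {
  stopifnot(nrow(candidates) >= 1,
            chosen >= 1, chosen <= nrow(candidates))
  if (any(!is.finite(candidates$H)) || any(candidates$H <= 0))
    stop("all candidates must have finite positive H")
  if (nrow(candidates) > 1 && any(candidates$C <= 0))
    stop("multi-candidate event with non-positive connectivity")
  structure(list(candidates = candidates, chosen = as.integer(chosen),
                 female_id = female_id, site = site,
                 decision_date = decision_date),
            class = "choice_event")
}

#' Conditional-logit choice probabilities
#'
#' Each candidate male's attractiveness is the power function
#' \eqn{A_i = H_i^{\alpha_1} C_i^{\alpha_2}} and the probability that the
#' female chooses him is \eqn{p_i = A_i / \sum_j A_j} over the real males
#' in her choice set (playbacks never appear as candidates). At
#' \eqn{\alpha_1 = \alpha_2 = 0} every \eqn{A_i = 1} and the probabilities
#' are uniform. Computed on the log scale for numerical stability, so
#' rescaling all H (or all C) by a common factor leaves the probabilities
#' exactly unchanged.
#'
#' @param event a [choice_event()].
#' @param alpha1 habitat exponent.
#' @param alpha2 connectivity exponent.
#' @return Numeric vector of probabilities summing to 1; a single-candidate
#'   event returns \code{1}.
#' @export
choice_probabilities <- function(event, alpha1, alpha2) {
  n <- nrow(event$candidates)
  if (n == 1) return(1)
  s <- alpha1 * log(event$candidates$H) + alpha2 * log(event$candidates$C)
  if (any(!is.finite(s))) stop("non-finite attractiveness score")
  e <- exp(s - max(s))
  e / sum(e)
}

#' Log-likelihood of observed choices
#'
#' \eqn{\ell(\alpha_1, \alpha_2) = \sum_{events} \ln p_{chosen}}: the joint
#' log-probability of every female's observed choice under the
#' conditional-logit model. Single-candidate events contribute exactly 0.
#'
#' @param events a list of [choice_event()]s (class
#'   \code{"choice_events"} or plain list).
#' @inheritParams choice_probabilities
#' @return A scalar \eqn{\le 0}.
#' @export
choice_loglik <- function(events, alpha1, alpha2) {
  f <- flatten_events(events)
  choice_loglik_flat(f, alpha1, alpha2)
}

# Internal flat layout used by the optimiser: one row per candidate with
# event index, log H, log C (centred within event), and the chosen
# indicator. The conditional likelihood is exactly invariant to per-event
# shifts of the log covariates, so centring changes no likelihood value
# while keeping exp() in range without per-group max bookkeeping.
flatten_events <- function(events) {
  ns <- vapply(events, function(e) nrow(e$candidates), integer(1))
  ev <- rep.int(seq_along(events), ns)
  lH <- log(unlist(lapply(events, function(e) e$candidates$H)))
  C <- unlist(lapply(events, function(e) e$candidates$C))
  lC <- log(C)
  # single-candidate events may have C = 0; their one term cancels in the
  # conditional likelihood, so the placeholder value never matters
  lC[!is.finite(lC)] <- 0
  chosen <- unlist(lapply(seq_along(events), function(i) {
    z <- logical(ns[i]); z[events[[i]]$chosen] <- TRUE; z
  }))
  if (any(!is.finite(lH))) stop("non-positive H in events")
  lH <- lH - rep.int(as.vector(rowsum(lH, ev)) / ns, ns)
  lC <- lC - rep.int(as.vector(rowsum(lC, ev)) / ns, ns)
  list(ev = ev, lH = lH, lC = lC, chosen = which(chosen),
       ends = cumsum(ns), n_events = length(events))
}

choice_loglik_flat <- function(f, alpha1, alpha2) {
  s <- alpha1 * f$lH + alpha2 * f$lC
  # rows are contiguous per event: per-event sums via cumsum differences
  cs <- cumsum(exp(s))  # >= 1 per event: s is centred within events
  sum(s[f$chosen]) - sum(log(diff(c(0, cs[f$ends]))))
}

#' Fit the conditional-logit mate-choice model
#'
#' Maximum-likelihood estimation of the attractiveness exponents. The four
#' candidate models free different subsets of the exponents:
#' \describe{
#'   \item{\code{"null"}}{\eqn{\alpha_1 = \alpha_2 = 0} fixed (k = 0).}
#'   \item{\code{"hab"}}{\eqn{\alpha_1} free, \eqn{\alpha_2 = 0}.}
#'   \item{\code{"connectivity"}}{\eqn{\alpha_2} free, \eqn{\alpha_1} = 0.}
#'   \item{\code{"hab + connectivity"}}{both free.}
#' }
#' Free exponents are unconstrained (no sign restriction) and maximised by
#' derivative-free Nelder-Mead simplex search with multiple starts at
#' -1, -0.5, 0, 0.5 and 1 per free parameter; the best of the restarts is
#' kept. AICc uses the number of choice events as the sample size and the
#' number of free exponents as k.
#'
#' @param events list of [choice_event()]s.
#' @param model one of \code{"null"}, \code{"hab"}, \code{"connectivity"},
#'   \code{"hab + connectivity"}.
#' @param starts numeric vector of start values tried for each free
#'   parameter.
#' @return Object of class \code{"mate_choice_fit"}: \code{alpha1},
#'   \code{alpha2}, \code{loglik}, \code{n_events}, \code{k}, \code{aicc},
#'   \code{model}, \code{convergence} (0 = converged).
#' @export
fit_mate_choice <- function(events,
                            model = c("hab + connectivity", "null", "hab",
                                      "connectivity"),
                            starts = c(-1, -0.5, 0, 0.5, 1)) {
  model <- match.arg(model)
  f <- flatten_events(events)
  n <- f$n_events
  free <- switch(model,
                 "null" = c(FALSE, FALSE),
                 "hab" = c(TRUE, FALSE),
                 "connectivity" = c(FALSE, TRUE),
                 "hab + connectivity" = c(TRUE, TRUE))
  k <- sum(free)
  if (k > 0 && all(tabulate(f$ev, nbins = n) <= 1))
    stop("likelihood is flat: every event has a single candidate")
  negll <- function(par) {
    a <- c(0, 0); a[free] <- par
    -choice_loglik_flat(f, a[1], a[2])
  }
  if (k == 0) {
    ll <- choice_loglik_flat(f, 0, 0)
    fit <- list(par = numeric(0), value = -ll, convergence = 0L)
  } else {
    best <- NULL
    for (s0 in starts) {
      o <- suppressWarnings(
        stats::optim(rep(s0, k), negll, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-10)))
      # polish: restart the simplex at the incumbent optimum
      o <- suppressWarnings(
        stats::optim(o$par, negll, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12)))
      if (is.null(best) || o$value < best$value - 1e-10) best <- o
    }
    fit <- best
  }
  a <- c(0, 0); a[free] <- fit$par
  ll <- -fit$value
  structure(list(alpha1 = a[1], alpha2 = a[2], loglik = ll,
                 n_events = n, k = k, aicc = aicc(ll, k, n),
                 model = model, free = free,
                 convergence = fit$convergence),
            class = "mate_choice_fit")
}

#' @export
print.mate_choice_fit <- function(x, ...) {
  cat(sprintf("mate-choice model '%s': %d events\n", x$model, x$n_events))
  cat(sprintf("  alpha1 (habitat)      = %8.4f%s\n", x$alpha1,
              if (x$free[1]) "" else "  (fixed)"))
  cat(sprintf("  alpha2 (connectivity) = %8.4f%s\n", x$alpha2,
              if (x$free[2]) "" else "  (fixed)"))
  cat(sprintf("  logLik %.3f   AICc %.2f (k = %d, n = %d)\n",
              x$loglik, x$aicc, x$k, x$n_events))
  invisible(x)
}

#' Fit all four mate-choice candidate models
#'
#' @inheritParams fit_mate_choice
#' @return List with \code{fits} (named list of [fit_mate_choice()]
#'   results in the order null, hab, connectivity, hab + connectivity) and
#'   \code{comparison} (AICc table, see [delta_and_weights()]).
#' @export
fit_mate_choice_set <- function(events, starts = c(-1, -0.5, 0, 0.5, 1)) {
  labs <- c("null", "hab", "connectivity", "hab + connectivity")
  fits <- lapply(labs, function(m) fit_mate_choice(events, m, starts))
  names(fits) <- labs
  av <- vapply(fits, `[[`, numeric(1), "aicc")
  list(fits = fits, comparison = delta_and_weights(av))
}
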