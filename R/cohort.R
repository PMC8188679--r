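#' Immunohistochemistry H-score (0-30)
#'
#' Staining is read as an intensity (negative 0, weak 1, moderate 2, strong
#' 3) and an extension of the stained area in 10% cut-offs; the score is
#' their product with the extension expressed in tenths, giving an integer in
#' `[0, 30]`.
#'
#' @param intensity Integer vector in `{0, 1, 2, 3}`.
#' @param extension_percent Percent vector in `[0, 100]`, multiples of 10.
#'   Intensity 0 must pair with extension 0 and vice versa.
#' @return Integer scores in `[0, 30]`.
#' @examples
#' ihc_score(3, 100)  # 30
#' ihc_score(2, 50)   # 10
#' @export
ihc_score <- function(intensity, extension_percent) {
  if (any(!intensity %in% 0:3)) {
    stop("intensity must be 0, 1, 2 or 3", call. = FALSE)
  }
  if (any(extension_percent < 0 | extension_percent > 100 |
            extension_percent %% 10 != 0)) {
    stop("extension must be a multiple of 10 in [0, 100]", call. = FALSE)
  }
  if (any((intensity == 0) != (extension_percent == 0))) {
    stop("intensity is 0 exactly when extension is 0", call. = FALSE)
  }
  as.integer(intensity * extension_percent / 10)
}

#' Membrane/cytoplasm ratio by tumour stage
#'
#' Among positive cases of each stage, the number showing membrane (and
#' cytoplasm) staining divided by the number showing cytoplasm-only staining.
#' Stages with no cytoplasm-only cases are reported as undefined (`NA` ratio
#' with `undefined = TRUE`), not infinity.
#'
#' @param cohort A cohort tibble (see [read_cohort()]).
#' @return A tibble with `stage`, `n_membrane`, `n_cytoplasm`, `ratio`,
#'   `undefined`.
#' @export
membrane_cytoplasm_ratio <- function(cohort) {
  positive <- cohort[cohort$location != "negative", , drop = FALSE]
  out <- positive |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(
      n_membrane = sum(.data$location == "membrane_and_cytoplasm"),
      n_cytoplasm = sum(.data$location == "cytoplasm"),
      .groups = "drop"
    )
  out$undefined <- out$n_cytoplasm == 0
  out$ratio <- ifelse(out$undefined, NA_real_, out$n_membrane / out$n_cytoplasm)
  stage_order <- c("Ta", "T1", "T2", "T3", "T4", "MET")
  out[order(match(out$stage, stage_order)),
      c("stage", "n_membrane", "n_cytoplasm", "ratio", "undefined")]
}

#' Association test for a 2x2 contingency table
#'
#' Pearson chi-square (no continuity correction by default) or Fisher's exact
#' test (two-sided by the minimum-likelihood rule). With `method = "auto"`
#' Fisher is selected exactly when any cell holds fewer than 5 individuals.
#'
#' @param table A 2x2 matrix of non-negative integer counts.
#' @param method `"auto"`, `"chi2"` or `"fisher"`.
#' @param correct Apply Yates continuity correction to the chi-square
#'   (default FALSE).
#' @return A tibble with `method`, `statistic` (NA for Fisher) and `p_value`.
#' @examples
#' association_test(matrix(c(10, 10, 10, 10), 2))
#' association_test(matrix(c(1, 8, 9, 2), 2))  # auto-selects Fisher
#' @export
association_test <- function(table, method = c("auto", "chi2", "fisher"),
                             correct = FALSE) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) || any(table != trunc(table))) {
    stop("need a 2x2 table of non-negative integer counts", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate table: a margin is zero", call. = FALSE)
  }
  if (method == "auto") method <- if (any(table < 5)) "fisher" else "chi2"
  if (method == "fisher") {
    p <- stats::fisher.test(table)$p.value
    tibble::tibble(method = "fisher", statistic = NA_real_, p_value = p)
  } else {
    ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
    tibble::tibble(method = "chi2", statistic = unname(ct$statistic),
                   p_value = ct$p.value)
  }
}

#' Kaplan-Meier curves and log-rank test by group
#'
#' Product-limit survival estimates per group under right censoring, the
#' log-rank test from observed-vs-expected events summed over distinct event
#' times (chi-square with groups - 1 degrees of freedom), and per-group
#' restricted mean survival times (the area under each curve up to the
#' largest observed time in the cohort).
#'
#' @param data A data frame with one row per subject.
#' @param group Name of the grouping column.
#' @param time,event Names of the follow-up time and event-indicator columns
#'   (defaults `followup_months`, `event`).
#' @return A `survival_fit` list: `curves` (tibble `group`, `time`, `n_risk`,
#'   `n_event`, `survival`), `groups` (per-group n, events, restricted mean),
#'   `logrank` (statistic, df, p_value; p is `NA` when no events occurred).
#' @export
km_logrank <- function(data, group = "group", time = "followup_months",
                       event = "event") {
  g <- as.character(data[[group]])
  t <- as.numeric(data[[time]])
  d <- as.integer(data[[event]])
  if (length(unique(g)) < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(g) == 0)) stop("empty group", call. = FALSE)

  tmax <- max(t)
  groups <- sort(unique(g))
  curves <- purrr::map_dfr(groups, function(gr) {
    tg <- t[g == gr]; dg <- d[g == gr]
    etimes <- sort(unique(tg[dg == 1]))
    surv <- 1
    rows <- tibble::tibble(time = numeric(0), n_risk = integer(0),
                           n_event = integer(0), survival = numeric(0))
    if (length(etimes) > 0) {
      rows <- purrr::map_dfr(etimes, function(tt) {
        n_risk <- sum(tg >= tt)
        n_event <- sum(tg == tt & dg == 1)
        surv <<- surv * (1 - n_event / n_risk)
        tibble::tibble(time = tt, n_risk = n_risk, n_event = n_event,
                       survival = surv)
      })
    }
    dplyr::mutate(rows, group = gr, .before = 1)
  })

  rmean <- purrr::map_dbl(groups, function(gr) {
    cg <- curves[curves$group == gr, ]
    steps <- rbind(data.frame(time = 0, survival = 1),
                   cg[, c("time", "survival")])
    steps <- steps[steps$time <= tmax, , drop = FALSE]
    sum(diff(c(steps$time, tmax)) * steps$survival)
  })
  group_summary <- tibble::tibble(
    group = groups,
    n = as.integer(table(factor(g, groups))),
    n_events = vapply(groups, function(gr) sum(d[g == gr]), numeric(1)),
    restricted_mean = rmean
  )

  # log-rank over distinct event times pooled across groups
  etimes <- sort(unique(t[d == 1]))
  G <- length(groups)
  U <- numeric(G)
  V <- matrix(0, G, G)
  O <- numeric(G)
  for (tt in etimes) {
    at_risk <- t >= tt
    n_j <- sum(at_risk)
    d_j <- sum(t == tt & d == 1)
    n_gj <- vapply(groups, function(gr) sum(at_risk & g == gr), numeric(1))
    d_gj <- vapply(groups, function(gr) sum(t == tt & d == 1 & g == gr), numeric(1))
    e_gj <- n_gj * d_j / n_j
    O <- O + d_gj
    U <- U + (d_gj - e_gj)
    if (n_j > 1) {
      frac <- n_gj / n_j
      vmat <- d_j * (n_j - d_j) / (n_j - 1) * (diag(frac) - outer(frac, frac))
      V <- V + vmat
    }
  }
  if (sum(d) == 0) {
    logrank <- tibble::tibble(statistic = NA_real_, df = G - 1, p_value = NA_real_)
  } else {
    Ur <- U[-G]
    Vr <- V[-G, -G, drop = FALSE]
    stat <- tryCatch(drop(t(Ur) %*% solve(Vr, Ur)), error = function(e) NA_real_)
    logrank <- tibble::tibble(
      statistic = stat, df = G - 1,
      p_value = if (is.na(stat)) NA_real_ else
        stats::pchisq(stat, G - 1, lower.tail = FALSE)
    )
  }

  structure(list(curves = curves, groups = group_summary, logrank = logrank,
                 observed = stats::setNames(O, groups)),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat("Kaplan-Meier fit,", nrow(x$groups), "groups\n")
  print(x$groups)
  cat(sprintf("log-rank chi-square = %.4g on %d df, p = %.4g\n",
              x$logrank$statistic, x$logrank$df, x$logrank$p_value))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname km_logrank
#' @param x A `survival_fit`.
#' @param ... Unused.
#' @export
tidy.survival_fit <- function(x, ...) x$curves

#' @rdname km_logrank
#' @export
glance.survival_fit <- function(x, ...) {
  tibble::tibble(
    n_groups = nrow(x$groups),
    n = sum(x$groups$n),
    n_events = sum(x$groups$n_events),
    statistic = x$logrank$statistic,
    df = x$logrank$df,
    p_value = x$logrank$p_value
  )
}

#' @rdname km_logrank
#' @export
autoplot.survival_fit <- function(x, ...) {
  start <- dplyr::distinct(x$curves, .data$group) |>
    dplyr::mutate(time = 0, survival = 1)
  dat <- dplyr::bind_rows(start,
                          x$curves[, c("group", "time", "survival")])
  ggplot2::ggplot(dat, ggplot2::aes(.data$time, .data$survival,
                                    colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival probability",
                  title = sprintf("Kaplan-Meier (log-rank p = %.3g)",
                                  x$logrank$p_value)) +
    ggplot2::theme_minimal()
}

#' Cox proportional-hazards regression
#'
#' Maximizes the Cox partial likelihood by Newton-Raphson with Efron handling
#' of tied event times. Convergence is declared when the relative change in
#' the partial log-likelihood falls below `tol` (default 1e-9) within
#' `max_iter` iterations; non-convergence and monotone-likelihood escapes are
#' flagged in the result rather than reported silently.
#'
#' @param data A data frame with one row per subject.
#' @param covariates Character vector of covariate column names; factors and
#'   character columns are expanded to treatment-contrast dummies.
#' @param time,event Names of the follow-up time and event columns.
#' @param tol,max_iter Convergence controls.
#' @return A `cox_fit` list with `terms` (tibble: `term`, `estimate` = log
#'   hazard ratio, `hazard_ratio`, `std_error`, `statistic`, `p_value`),
#'   `loglik`, `n`, `n_events`, `converged`, `flag`.
#' @export
cox_fit <- function(data, covariates, time = "followup_months", event = "event",
                    tol = 1e-9, max_iter = 50) {
  t_ <- as.numeric(data[[time]])
  d_ <- as.integer(data[[event]])
  if (sum(d_) < 1) stop("need at least one event", call. = FALSE)
  X <- stats::model.matrix(
    stats::reformulate(covariates),
    data = as.data.frame(data)
  )[, -1, drop = FALSE]
  p <- ncol(X)
  if (p == 0) stop("no covariate columns after expansion", call. = FALSE)
  # a constant covariate carries no information: HR 1, p 1, flagged
  if (all(apply(X, 2, function(v) diff(range(v)) == 0))) {
    terms <- tibble::tibble(
      term = colnames(X), estimate = 0, hazard_ratio = 1,
      std_error = NA_real_, statistic = NA_real_, p_value = 1
    )
    return(structure(list(terms = terms, loglik = NA_real_, n = length(t_),
                          n_events = sum(d_), converged = TRUE,
                          flag = "no_information",
                          var = matrix(NA_real_, p, p)),
                     class = "cox_fit"))
  }

  ord <- order(t_)
  t_ <- t_[ord]; d_ <- d_[ord]; X <- X[ord, , drop = FALSE]
  etimes <- unique(t_[d_ == 1])

  loglik_grad_hess <- function(beta) {
    eta <- drop(X %*% beta)
    w <- exp(eta)
    ll <- 0
    U <- numeric(p)
    H <- matrix(0, p, p)
    for (tt in etimes) {
      risk <- which(t_ >= tt)
      dead <- which(t_ == tt & d_ == 1)
      dd <- length(dead)
      S0 <- sum(w[risk])
      S1 <- drop(crossprod(X[risk, , drop = FALSE], w[risk]))
      S2 <- crossprod(X[risk, , drop = FALSE], X[risk, , drop = FALSE] * w[risk])
      s0 <- sum(w[dead])
      s1 <- drop(crossprod(X[dead, , drop = FALSE], w[dead]))
      s2 <- crossprod(X[dead, , drop = FALSE], X[dead, , drop = FALSE] * w[dead])
      ll <- ll + sum(eta[dead])
      for (l in seq_len(dd) - 1) {
        f <- l / dd
        D0 <- S0 - f * s0
        D1 <- S1 - f * s1
        D2 <- S2 - f * s2
        ll <- ll - log(D0)
        U <- U - D1 / D0
        H <- H + (D2 / D0 - tcrossprod(D1) / D0^2)
      }
      U <- U + colSums(X[dead, , drop = FALSE])
    }
    list(ll = ll, U = U, H = H)
  }

  beta <- numeric(p)
  converged <- FALSE
  flag <- NA_character_
  prev <- loglik_grad_hess(beta)
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(prev$H, prev$U), error = function(e) NULL)
    if (is.null(step)) { flag <- "singular_information"; break }
    beta_new <- beta + step
    cur <- loglik_grad_hess(beta_new)
    # step-halving if the likelihood worsens
    halvings <- 0
    while (cur$ll < prev$ll && halvings < 20) {
      beta_new <- (beta + beta_new) / 2
      cur <- loglik_grad_hess(beta_new)
      halvings <- halvings + 1
    }
    rel <- abs(cur$ll - prev$ll) / max(abs(prev$ll), 1e-12)
    beta <- beta_new
    done <- rel < tol
    prev <- cur
    if (done) { converged <- TRUE; break }
  }
  if (any(abs(beta) > 15)) flag <- "monotone_likelihood"
  if (!converged && is.na(flag)) flag <- "max_iterations"

  info <- prev$H
  var_beta <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(diag(var_beta))
  z <- beta / se
  terms <- tibble::tibble(
    term = colnames(X),
    estimate = unname(beta),
    hazard_ratio = exp(unname(beta)),
    std_error = unname(se),
    statistic = unname(z),
    p_value = 2 * stats::pnorm(-abs(unname(z)))
  )
  structure(list(terms = terms, loglik = prev$ll, n = length(t_),
                 n_events = sum(d_), converged = converged, flag = flag,
                 var = var_beta),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit: n = %d, events = %d, loglik = %.4f%s\n",
              x$n, x$n_events, x$loglik,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  print(x$terms)
  invisible(x)
}

#' @rdname cox_fit
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @export
tidy.cox_fit <- function(x, ...) x$terms

#' @rdname cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, loglik = x$loglik,
                 converged = x$converged, flag = x$flag)
}
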