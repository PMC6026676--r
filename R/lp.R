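#' Linear-programming core
#'
#' Every analysis in the package reduces to linear programs of the form
#' \deqn{\min/\max\; c'x \quad \mathrm{s.t.}\; A x = b,\; l \le x \le u,}
#' the canonical shape of flux balance analysis (steady-state mass balance
#' plus flux bounds).  Two interchangeable backends are provided:
#' a native bounded-variable two-phase simplex written in R (`"simplex"`,
#' the default) and a bridge to `scipy.optimize.linprog` (HiGHS) through a
#' `python` subprocess (`"scipy"`).  Results must agree to 1e-6; the test
#' suite enforces this on randomized problems.
#'
#' @param A constraint matrix (dense or `Matrix` sparse; coerced to dense).
#' @param b right-hand side vector.
#' @param c_vec objective coefficient vector.
#' @param lb,ub variable lower/upper bounds (may be +/-Inf one-sided).
#' @param sense `"min"` or `"max"`.
#' @return an object of class `lp_problem`.
#' @keywords internal
lp_problem <- function(A, b, c_vec, lb, ub, sense = c("max", "min")) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  n <- ncol(A)
  stopifnot(length(b) == nrow(A), length(c_vec) == n,
            length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) {
    stop("lp_problem: lower bound exceeds upper bound for variable(s) ",
         paste(which(lb > ub + 1e-12), collapse = ", "))
  }
  structure(list(A = A, b = as.numeric(b), c = as.numeric(c_vec),
                 lb = as.numeric(lb), ub = as.numeric(ub), sense = sense),
            class = "lp_problem")
}

#' Solve a linear program
#'
#' @param lp an [lp_problem()].
#' @param solver `"simplex"` (native) or `"scipy"`; defaults to
#'   `getOption("fluxscope.solver", "simplex")`.
#' @param tol pivot/optimality tolerance of the native solver.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `objective` (NA unless optimal) and `x` (primal solution, NA unless
#'   optimal).
#' @export
solve_lp <- function(lp, solver = getOption("fluxscope.solver", "simplex"),
                     tol = 1e-9) {
  stopifnot(inherits(lp, "lp_problem"))
  switch(solver,
         simplex = lp_solve_simplex(lp, tol = tol),
         scipy   = lp_solve_scipy(lp),
         stop("unknown LP solver: ", solver))
}

# Bounded-variable two-phase primal simplex, full tableau.
# Nonbasic variables rest at a bound (or at 0 when free); entering steps are
# limited by basic-variable bounds or by a bound flip of the entering
# variable.  Dantzig pricing with a deterministic switch to Bland's rule
# guards against cycling; all tie-breaks are by lowest index, so the solver
# is fully deterministic.
lp_solve_simplex <- function(lp, tol = 1e-9) {
  A <- lp$A
  m <- nrow(A); n <- ncol(A)
  minimize <- lp$sense == "min"
  cc <- if (minimize) lp$c else -lp$c

  lb_all <- c(lp$lb, rep(0, m))
  ub_all <- c(lp$ub, rep(Inf, m))
  x_all <- numeric(n + m)
  stat <- integer(n + m)              # 1 at lb, 2 at ub, 3 free at 0
  for (j in seq_len(n)) {
    if (is.finite(lb_all[j])) { x_all[j] <- lb_all[j]; stat[j] <- 1L }
    else if (is.finite(ub_all[j])) { x_all[j] <- ub_all[j]; stat[j] <- 2L }
    else { x_all[j] <- 0; stat[j] <- 3L }
  }

  r <- lp$b - as.vector(A %*% x_all[seq_len(n)])
  sg <- ifelse(r < 0, -1, 1)
  TT <- cbind(A * sg, diag(m))
  basis <- n + seq_len(m)
  inbasis <- logical(n + m); inbasis[basis] <- TRUE
  x_all[basis] <- abs(r)
  xB <- x_all[basis]

  structural <- c(rep(TRUE, n), rep(FALSE, m))
  movable <- (ub_all - lb_all) > tol    # fixed variables never enter

  run_phase <- function(costs, eligible) {
    bland_after <- 50L * (m + n) + 200L
    iter_max <- 500L * (m + n) + 2000L
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > iter_max) stop("simplex: iteration limit reached")
      d <- costs - as.vector(crossprod(costs[basis], TT))
      d[basis] <- 0
      cand <- eligible & !inbasis & movable &
        ((stat == 1L & d < -tol) | (stat == 2L & d > tol) |
           (stat == 3L & abs(d) > tol))
      if (!any(cand)) return(list(status = "optimal", iter = iter))
      idx <- which(cand)
      j <- if (iter > bland_after) idx[1L] else idx[which.max(abs(d[idx]))]
      s <- if (d[j] < 0) 1 else -1     # direction of change of x_j
      swi <- s * TT[, j]

      lim <- rep(Inf, m)
      pos <- swi > tol
      neg <- swi < -tol
      lbB <- lb_all[basis]; ubB <- ub_all[basis]
      lim[pos] <- (xB[pos] - lbB[pos]) / swi[pos]
      lim[neg] <- (ubB[neg] - xB[neg]) / (-swi[neg])
      lim[lim < 0] <- 0
      t_basic <- if (m > 0) min(lim) else Inf
      t_flip <- ub_all[j] - lb_all[j]  # Inf when one-sided/free
      if (!is.finite(t_basic) && !is.finite(t_flip)) {
        return(list(status = "unbounded", iter = iter))
      }
      if (t_flip < t_basic - tol) {    # bound flip, no basis change
        x_all[j] <<- if (stat[j] == 1L) ub_all[j] else lb_all[j]
        stat[j] <<- if (stat[j] == 1L) 2L else 1L
        xB <<- xB - t_flip * swi
        x_all[basis] <<- xB
        next
      }
      tstep <- t_basic
      ties <- which(lim <= t_basic + 1e-10)
      if (iter > bland_after) {
        rpiv <- ties[which.min(basis[ties])]
      } else {
        rpiv <- ties[which.max(abs(swi[ties]))]
      }
      leaving <- basis[rpiv]
      leave_to <- if (swi[rpiv] > 0) 1L else 2L
      x_all[leaving] <<- if (leave_to == 1L) lb_all[leaving] else ub_all[leaving]
      stat[leaving] <<- leave_to
      inbasis[leaving] <<- FALSE

      xB <<- xB - tstep * swi
      enter_val <- x_all[j] + s * tstep
      piv <- TT[rpiv, j]
      TT[rpiv, ] <<- TT[rpiv, ] / piv
      colj <- TT[, j]; colj[rpiv] <- 0
      TT <<- TT - outer(colj, TT[rpiv, ])
      basis[rpiv] <<- j
      inbasis[j] <<- TRUE
      xB[rpiv] <<- enter_val
      x_all[basis] <<- xB
    }
  }

  # Phase 1: minimize sum of artificials.
  if (m > 0 && sum(xB) > 0) {
    c1 <- c(rep(0, n), rep(1, m))
    ph1 <- run_phase(c1, eligible = rep(TRUE, n + m))
    if (ph1$status != "optimal") stop("simplex: phase-1 failure")
    if (sum(x_all[(n + 1):(n + m)]) > 1e-7) {
      return(list(status = "infeasible", objective = NA_real_, x = NULL))
    }
  }
  # Drive residual artificials out of the basis (degenerate pivots) or pin
  # them to zero on redundant rows.
  for (i in seq_len(m)) {
    if (basis[i] > n) {
      row <- TT[i, seq_len(n)]
      jrep <- which(abs(row) > 1e-7 & !inbasis[seq_len(n)])
      if (length(jrep)) {
        j <- jrep[which.max(abs(row[jrep]))]
        leaving <- basis[i]
        inbasis[leaving] <- FALSE
        x_all[leaving] <- 0; stat[leaving] <- 1L
        ub_all[leaving] <- 0; movable[leaving] <- FALSE
        piv <- TT[i, j]
        TT[i, ] <- TT[i, ] / piv
        colj <- TT[, j]; colj[i] <- 0
        TT <- TT - outer(colj, TT[i, ])
        basis[i] <- j
        inbasis[j] <- TRUE
        xB[i] <- x_all[j]
        x_all[basis] <- xB
      } else {
        ub_all[basis[i]] <- 0          # redundant row: artificial stays 0
        movable[basis[i]] <- FALSE
      }
    }
  }

  c2 <- c(cc, rep(0, m))
  ph2 <- run_phase(c2, eligible = structural)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", objective = NA_real_, x = NULL))
  }

  x <- x_all[seq_len(n)]
  x <- pmin(pmax(x, lp$lb - 1e-7), lp$ub + 1e-7)  # shave numerical drift
  obj <- sum(lp$c * x)
  list(status = "optimal", objective = obj, x = x)
}

# scipy.optimize.linprog (HiGHS) bridge: one-shot python subprocess with
# JSON files for problem and answer.  Infinities travel as +/-1e30.
lp_solve_scipy <- function(lp) {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "") stop("scipy backend: no python interpreter on PATH")
  script <- system.file("python", "lp_solve.py", package = "fluxscope")
  if (script == "") {
    # during development (package loaded with load_all) fall back to source tree
    script <- file.path("inst", "python", "lp_solve.py")
  }
  cap <- function(v) { v[v == Inf] <- 1e30; v[v == -Inf] <- -1e30; v }
  cvec <- if (lp$sense == "min") lp$c else -lp$c
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(
    list(c = unname(cap(cvec)),
         A = lapply(seq_len(nrow(lp$A)), function(i) unname(lp$A[i, ])),
         b = lp$b, lb = cap(lp$lb), ub = cap(lp$ub)),
    fin, digits = NA, auto_unbox = FALSE)
  st <- system2(py, c(shQuote(script), shQuote(fin), shQuote(fout)),
                stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout)) {
    stop("scipy backend failed: ", paste(st, collapse = "\n"))
  }
  res <- jsonlite::read_json(fout, simplifyVector = TRUE)
  status <- switch(as.character(res$status),
                   "0" = "optimal", "2" = "infeasible", "3" = "unbounded",
                   "error")
  if (status != "optimal") {
    return(list(status = status, objective = NA_real_, x = NULL))
  }
  x <- as.numeric(res$x)
  list(status = "optimal", objective = sum(lp$c * x), x = x)
}
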