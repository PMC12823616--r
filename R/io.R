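#' Write a trajectory as CSV
#'
#' Serializes a solution or trajectory as CSV with columns `t, S, I, R` in
#' fixed 6-decimal formatting. Reading the file back reproduces the
#' trajectory bit-exactly at the serialized precision.
#'
#' @param x a `sir_solution` or a data.frame with columns `t`, `S`, `I`, `R`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_trajectory <- function(x, path) {
  if (inherits(x, "sir_solution")) x <- x$trajectory
  stopifnot(all(c("t", "S", "I", "R") %in% names(x)))
  out <- data.frame(t = sprintf("%.6f", x$t), S = sprintf("%.6f", x$S),
                    I = sprintf("%.6f", x$I), R = sprintf("%.6f", x$R))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV
#' @param path file written by [write_trajectory()].
#' @return data.frame with numeric columns `t`, `S`, `I`, `R`.
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path, colClasses = "numeric")
}

#' Write solver diagnostics as a JSON sidecar
#'
#' The sidecar echoes the full run configuration, so a run can be reproduced
#' from it exactly.
#'
#' @param sol a `sir_solution`.
#' @param path output file.
#' @param scenario optional scenario description to echo (e.g. the list
#'   returned by [sir_scenario()] or a config file path).
#' @return the path, invisibly.
#' @export
write_diagnostics <- function(sol, path, scenario = NULL) {
  p <- sol$params
  cfg <- sol$config
  obj <- list(
    solver = "wavelet_collocation",
    params = list(beta = p$beta, gamma = p$gamma, delta = p$delta,
                  alpha = p$alpha, tau = p$tau, N = p$N,
                  horizon = p$horizon),
    config = list(J = cfg$J, order = cfg$order, augment = cfg$augment,
                  method = cfg$method, residual_tol = cfg$residual_tol,
                  max_iter = cfg$max_iter, interp_order = cfg$interp_order,
                  output_points = cfg$output_points),
    basis = basis_summary(sol$problem$basis),
    diagnostics = list(iterations = sol$iterations,
                       residual_norm = sol$residual_norm,
                       conservation = sol$conservation,
                       converged = sol$converged))
  if (!is.null(scenario)) obj$scenario <- scenario
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

## scenario configuration files ------------------------------------------

.scenario_keys <- c("beta", "gamma", "delta", "alpha", "tau", "N", "horizon",
                    "history.S", "history.I", "history.R", "variant")

#' Read a scenario configuration file
#'
#' Flat key-value configuration in YAML or JSON (by file extension):
#' numeric fields `beta, gamma, delta, alpha, tau, N, horizon` and history
#' polynomials `history.S`, `history.I`, `history.R` as coefficient lists
#' (constant first). In YAML, dotted keys may be written either literally
#' (`history.S`) or as a nested `history:` section. Unknown keys are errors,
#' not warnings: a silently ignored typo in a rate name would invalidate a
#' run.
#'
#' @param path configuration file (`.yaml`, `.yml` or `.json`).
#' @return list with `params` ([sir_params()]) and `histories`
#'   ([history_set()]).
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("unsupported scenario format '.", ext,
                     "': use YAML or JSON"))
  if (!is.list(raw)) stop("malformed scenario file: ", path)
  ## flatten a nested history: section into dotted keys
  if (!is.null(raw$history) && is.list(raw$history)) {
    for (k in names(raw$history)) raw[[paste0("history.", k)]] <- raw$history[[k]]
    raw$history <- NULL
  }
  unknown <- setdiff(names(raw), .scenario_keys)
  if (length(unknown) > 0)
    stop("unknown scenario key(s): ", paste(unknown, collapse = ", "),
         " (accepted: ", paste(.scenario_keys, collapse = ", "), ")")
  need <- c("beta", "gamma", "delta", "alpha", "tau", "N", "horizon",
            "history.S", "history.I", "history.R")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0)
    stop("scenario file missing key(s): ", paste(missing, collapse = ", "))
  num <- function(k) {
    v <- raw[[k]]
    if (!is.numeric(v) || length(v) != 1L)
      stop("scenario key `", k, "` must be a single number")
    v
  }
  params <- sir_params(num("beta"), num("gamma"), num("delta"),
                       num("alpha"), num("tau"), num("N"), num("horizon"))
  hist <- lapply(c("history.S", "history.I", "history.R"), function(k) {
    v <- raw[[k]]
    if (!is.numeric(v)) stop("scenario key `", k,
                             "` must be a numeric coefficient list")
    as.numeric(v)
  })
  list(params = params,
       histories = history_set(hist[[1]], hist[[2]], hist[[3]], params$tau))
}

#' Write a scenario configuration file
#' @param params a [sir_params()] object.
#' @param history_coefs list with numeric coefficient vectors `S`, `I`, `R`
#'   (constant first).
#' @param path output file (`.yaml`/`.yml` or `.json`).
#' @return the path, invisibly.
#' @export
write_scenario <- function(params, history_coefs, path) {
  obj <- list(beta = params$beta, gamma = params$gamma,
              delta = params$delta, alpha = params$alpha, tau = params$tau,
              N = params$N, horizon = params$horizon,
              history = list(S = history_coefs$S, I = history_coefs$I,
                             R = history_coefs$R))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(obj, path)
  else if (ext == "json") jsonlite::write_json(obj, path, auto_unbox = TRUE,
                                               digits = NA, pretty = TRUE)
  else stop("unsupported scenario format '.", ext, "'")
  invisible(path)
}

#' Side-by-side comparison table of solutions
#'
#' Interpolates each solution at the requested times and lays the values out
#' like a published comparison table (4-decimal presentation); when exactly
#' two solutions are compared, a max-absolute-difference column is added.
#'
#' @param solutions named list of `sir_solution` or `sir_trajectory`
#'   objects.
#' @param times report times; must lie within every solution's horizon.
#' @param compartment `"S"`, `"I"` or `"R"`.
#' @return data.frame of values (one column per solver); attribute
#'   `formatted` holds an aligned text rendering.
#' @export
compare_table <- function(solutions, times, compartment = c("S", "I", "R")) {
  compartment <- match.arg(compartment)
  if (is.null(names(solutions)) || any(names(solutions) == ""))
    names(solutions) <- paste0("solver", seq_along(solutions))
  cols <- lapply(solutions, function(s) {
    tr <- if (inherits(s, "sir_solution")) s$trajectory else s
    if (min(times) < min(tr$t) - 1e-9 || max(times) > max(tr$t) + 1e-9)
      stop("requested time outside the solution horizon")
    stats::approx(tr$t, tr[[compartment]], xout = times)$y
  })
  out <- data.frame(t = times)
  for (nm in names(cols)) out[[nm]] <- cols[[nm]]
  if (length(cols) == 2)
    out$abs_diff <- abs(out[[2]] - out[[3]])
  fmt <- cbind(`Time (t)` = sprintf("%.1f", times),
               vapply(out[-1], function(v) sprintf("%.4f", v),
                      character(length(times))))
  attr(out, "formatted") <- paste(
    c(paste(colnames(fmt), collapse = "  "),
      apply(fmt, 1, paste, collapse = "  ")),
    collapse = "\n")
  out
}

## command-line interface -------------------------------------------------

## thin flag parser: --key value pairs plus one leading subcommand
.parse_cli <- function(args) {
  if (length(args) == 0) return(list(cmd = "help", opts = list()))
  cmd <- args[[1]]
  args <- args[-1]
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[[i + 1]], "--"))
      stop("flag --", key, " needs a value")
    opts[[key]] <- args[[i + 1]]
    i <- i + 2
  }
  list(cmd = cmd, opts = opts)
}

.cli_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) return(default)
  v <- suppressWarnings(as.numeric(opts[[key]]))
  if (is.na(v)) stop("flag --", key, " must be numeric, got: ", opts[[key]])
  v
}

.cli_scenario <- function(opts) {
  name <- if (is.null(opts$scenario)) "default" else opts$scenario
  if (name == "default") {
    if (is.null(opts$variant))
      stop("the built-in scenario requires an explicit --variant ",
           "{as_text|as_tables} (its history functions and tabulated ",
           "initial values disagree on I(0)/R(0))")
    sc <- sir_scenario(match.arg(opts$variant, c("as_text", "as_tables")),
                       beta = .cli_num(opts, "beta", 5e-4),
                       gamma = .cli_num(opts, "gamma", 0.1),
                       delta = .cli_num(opts, "delta", 0.05),
                       alpha = .cli_num(opts, "alpha", 0.9),
                       tau = .cli_num(opts, "tau", 2),
                       horizon = .cli_num(opts, "horizon", 10))
  } else {
    sc <- read_scenario(name)
    for (k in c("alpha", "beta", "gamma", "delta", "tau", "horizon")) {
      if (!is.null(opts[[k]])) {
        p <- sc$params
        p[[if (k == "horizon") "horizon" else k]] <- .cli_num(opts, k, NULL)
        sc$params <- do.call(sir_params,
                             p[c("beta", "gamma", "delta", "alpha", "tau",
                                 "N", "horizon")])
      }
    }
  }
  sc
}

.cli_config <- function(opts) {
  solver_config(J = .cli_num(opts, "level", 6),
                order = .cli_num(opts, "db-order", 4),
                residual_tol = .cli_num(opts, "tol", 1e-10),
                max_iter = .cli_num(opts, "max-iter", 50))
}

#' Command-line entry point
#'
#' Backs the `inst/cli/wavefdde.R` script. Subcommands: `run` (single
#' solve, writes a trajectory CSV and a JSON diagnostics sidecar), `sweep`
#' (one parameter over a value list, long-format CSV), `compare` (wavelet
#' collocation vs a reference solver at the tabulated report times),
#' `convergence` (refinement study on the Mittag-Leffler fixture) and
#' `selftest` (runs fast internal invariant checks). A `--seed` flag is
#' accepted for interface stability but unused: the solver is
#' deterministic.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status, invisibly (0 on success, 2 on usage or
#'   configuration errors, 1 on solver failure).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  parsed <- tryCatch(.parse_cli(args), error = function(e) e)
  if (inherits(parsed, "error")) {
    message("error: ", conditionMessage(parsed))
    return(invisible(2L))
  }
  status <- tryCatch(
    switch(parsed$cmd,
           run = .cli_run(parsed$opts),
           sweep = .cli_sweep(parsed$opts),
           compare = .cli_compare(parsed$opts),
           convergence = .cli_convergence(parsed$opts),
           selftest = .cli_selftest(parsed$opts),
           help = { .cli_help(); 0L },
           { message("unknown subcommand: ", parsed$cmd); .cli_help(); 2L }),
    error = function(e) {
      message("error: ", conditionMessage(e))
      if (grepl("scenario|flag|variant|key", conditionMessage(e))) 2L else 1L
    })
  invisible(as.integer(status))
}

.cli_help <- function() {
  message(
    "usage: wavefdde <run|sweep|compare|convergence|selftest> [flags]\n",
    "flags: --scenario {default|<file.yaml|.json>} --variant {as_text|as_tables}\n",
    "       --solver {hybrid|abm|rk4} --alpha --beta --gamma --delta --tau\n",
    "       --horizon --level J --db-order N --tol --max-iter --out PREFIX\n",
    "       --sweep name=v1,v2,... --times t1,t2,... --seed (accepted, unused)")
}

.cli_run <- function(opts) {
  sc <- .cli_scenario(opts)
  solver <- if (is.null(opts$solver)) "hybrid" else opts$solver
  out <- if (is.null(opts$out)) "wavefdde_run" else opts$out
  if (solver == "hybrid") {
    sol <- solve_sir(sc$params, sc$histories, .cli_config(opts))
    write_trajectory(sol, paste0(out, ".csv"))
    write_diagnostics(sol, paste0(out, ".json"),
                      scenario = opts$scenario)
    message(sprintf(
      "n_b = %d, %d iterations, residual %.3g, conservation %.3g",
      sol$problem$n_b, sol$iterations, sol$residual_norm,
      sol$conservation))
  } else {
    tr <- switch(solver,
                 abm = abm_fdde(sc$params, sc$histories,
                                h = .cli_num(opts, "step", 1e-3)),
                 rk4 = rk4_dde(sc$params, sc$histories,
                               h = .cli_num(opts, "step", 1e-3)),
                 stop("unknown solver: ", solver))
    write_trajectory(tr, paste0(out, ".csv"))
    jsonlite::write_json(list(solver = solver, h = attr(tr, "h")),
                         paste0(out, ".json"), auto_unbox = TRUE)
  }
  0L
}

.cli_sweep <- function(opts) {
  if (is.null(opts$sweep)) stop("sweep requires --sweep name=v1,v2,...")
  parts <- strsplit(opts$sweep, "=", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("malformed --sweep, expected name=v1,v2,...")
  values <- as.numeric(strsplit(parts[2], ",", fixed = TRUE)[[1]])
  if (any(is.na(values))) stop("non-numeric sweep values")
  sc <- .cli_scenario(opts)
  sw <- sweep_parameter(sc$params, sc$histories, parts[1], values,
                        .cli_config(opts))
  out <- if (is.null(opts$out)) "wavefdde_sweep" else opts$out
  rows <- list()
  for (i in seq_along(sw)) {
    s <- sw[[i]]
    if (inherits(s, "sir_sweep_failure")) {
      message("sweep value ", values[i], " failed: ", s$message)
      next
    }
    tr <- s$trajectory
    rows[[length(rows) + 1]] <-
      cbind(data.frame(value = values[i]), tr)
  }
  long <- do.call(rbind, rows)
  names(long)[1] <- parts[1]
  utils::write.csv(
    data.frame(lapply(long, function(v)
      if (is.numeric(v)) sprintf("%.6f", v) else v)),
    paste0(out, ".csv"), row.names = FALSE, quote = FALSE)
  if (any(vapply(sw, inherits, logical(1), "sir_sweep_failure"))) 1L else 0L
}

.cli_compare <- function(opts) {
  sc <- .cli_scenario(opts)
  times <- if (is.null(opts$times))
    c(0, 1, 2.5, 4, 5.5, 7, 8.5, 10) * sc$params$horizon / 10
  else as.numeric(strsplit(opts$times, ",", fixed = TRUE)[[1]])
  sol <- solve_sir(sc$params, sc$histories, .cli_config(opts))
  refname <- if (sc$params$alpha == 1) "rk4" else "abm"
  ref <- if (refname == "rk4") rk4_dde(sc$params, sc$histories, h = 1e-3)
  else abm_fdde(sc$params, sc$histories, h = 1e-3)
  for (comp in c("S", "I", "R")) {
    tab <- compare_table(stats::setNames(list(sol, ref),
                                         c("hybrid", refname)),
                         times, comp)
    message(comp, ":\n", attr(tab, "formatted"))
  }
  out <- if (is.null(opts$out)) NULL else opts$out
  if (!is.null(out)) {
    tab <- compare_table(stats::setNames(list(sol, ref),
                                         c("hybrid", refname)),
                         times, "I")
    utils::write.csv(format(tab, digits = 10), paste0(out, ".csv"),
                     row.names = FALSE, quote = FALSE)
  }
  0L
}

.cli_convergence <- function(opts) {
  alpha <- .cli_num(opts, "alpha", 0.7)
  pf <- ml_decay_problem(alpha, .cli_num(opts, "gamma", 0.1))
  cs <- convergence_study(pf, 4:7)
  message(paste(utils::capture.output(print(cs)), collapse = "\n"))
  message(sprintf("empirical order: %.2f", attr(cs, "order")))
  0L
}

.cli_selftest <- function(opts) {
  f <- daub_filter(4)
  stopifnot(abs(sum(f$coefficients) - sqrt(2)) < 1e-12)
  sh <- shift_matrix(seq(0, 1, 0.25), 0.5, interp_order = 1,
                     policy = "cyclic")
  stopifnot(sh$weights[1, 3] == 1)
  pr <- ml_decay_problem(0.7, 0.1)
  sol <- solve_sir(pr$params, pr$histories, solver_config(J = 5))
  err <- max(abs(sol$trajectory$I - pr$exact$I(sol$trajectory$t)) /
               pmax(abs(pr$exact$I(sol$trajectory$t)), 1e-10))
  stopifnot(sol$conservation < 1e-6, err < 1e-2)
  message("selftest passed (filter, shift matrix, relaxation fixture)")
  0L
}
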