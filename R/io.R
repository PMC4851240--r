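#' Read and write blinded stage-1 data as CSV
#'
#' The on-disk format is a plain CSV with header
#' `subject,x,y[,g][,block_id]` and a 0-based subject index. Floats are
#' serialized with 17 significant digits so a write/read round trip is
#' bit-identical.
#'
#' @param path File path.
#' @param scheme Optional randomization scheme used for validation: under
#'   `"random_allocation"` a present `g` column must contain exactly half
#'   ones.
#' @return `read_stage1_csv()` returns a tibble; `write_stage1_csv()`
#'   returns `path` invisibly.
#' @export
read_stage1_csv <- function(path, scheme = NULL) {
  stopifnot(file.exists(path))
  d <- utils::read.csv(path, colClasses = NA)
  for (col in c("subject", "x", "y")) {
    if (!col %in% names(d)) {
      stop(sprintf("stage-1 CSV is missing required column `%s`", col),
           call. = FALSE)
    }
  }
  allowed <- c("subject", "x", "y", "g", "block_id")
  extra <- setdiff(names(d), allowed)
  if (length(extra)) {
    stop("unknown columns in stage-1 CSV: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  for (col in intersect(allowed, names(d))) {
    if (!is.numeric(d[[col]])) {
      stop(sprintf("column `%s` must be numeric", col), call. = FALSE)
    }
  }
  if ("g" %in% names(d)) {
    if (!all(d$g %in% c(0, 1))) {
      stop("column `g` must contain only 0/1", call. = FALSE)
    }
    if (identical(scheme, "random_allocation") &&
        sum(d$g) != nrow(d) / 2) {
      stop("under random allocation `g` must sum to n1/2", call. = FALSE)
    }
  }
  tibble::as_tibble(d)
}

#' @rdname read_stage1_csv
#' @param data A stage-1 data frame (columns `subject`, `x`, `y`, optional
#'   `g`, `block_id`).
#' @export
write_stage1_csv <- function(data, path) {
  stopifnot(is.data.frame(data),
            all(c("subject", "x", "y") %in% names(data)))
  out <- data
  for (col in c("x", "y")) out[[col]] <- format_float(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

format_float <- function(v) {
  out <- sprintf("%.17g", v)
  out[is.na(v)] <- "NA"
  out
}

#' Write a results table with a reproducibility stanza
#'
#' Writes any results tibble as CSV (floats at 17 significant digits) and
#' a JSON sidecar `<path>.meta.json` carrying the seed, package version
#' and a hash of the generating configuration, so a results file can
#' always be traced back to the run that produced it.
#'
#' @param table A data frame of results.
#' @param path Output CSV path.
#' @param config Optional list describing the run (echoed into the hash).
#' @param seed Seed used for the run.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(table, path, config = NULL, seed = NULL) {
  stopifnot(is.data.frame(table))
  out <- table
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], format_float)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  meta <- list(
    package = "blindsr",
    version = as.character(utils::packageVersion("blindsr")),
    seed = seed,
    config_hash = config_hash(config),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  writeLines(to_json(meta), paste0(path, ".meta.json"))
  invisible(path)
}

# minimal JSON encoder for the flat metadata stanza
to_json <- function(x) {
  enc <- function(v) {
    if (is.null(v)) return("null")
    if (is.numeric(v)) return(format(v, digits = 15))
    paste0("\"", gsub("\"", "\\\\\"", as.character(v)), "\"")
  }
  paste0("{", paste0("\"", names(x), "\": ",
                     vapply(x, enc, character(1)), collapse = ", "), "}")
}

# FNV-1a hash over the deparsed configuration; kept in doubles because the
# 32-bit state exceeds R's integer range (xor applied on the low byte)
config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  s <- paste(deparse(config), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration for the simulation drivers, validates every
#' field (unknown keys are rejected, errors name the offending field) and
#' fills defaults: `alpha = 0.025`, `n_runs = 200000`, `seed = 1`,
#' `scheme = "random_allocation"`, `n2min = 0`, `n2max = Inf` (the string
#' `"Inf"`, `.inf` or omission all denote an unrestricted second stage).
#'
#' @param path Path to a YAML file with keys among: `params`
#'   (`mu0,mu1,nu0,nu1,sigma,rho` or `endpoint: lymphocyte|wbc` preset),
#'   `n1`, `n2min`, `n2max`, `alpha`, `scheme`, `tau`, `n_runs`, `seed`,
#'   plus optional driver-specific keys `rho_grid`, `effect_grid`, `test`,
#'   `rule`, `out`.
#' @return A list with elements `params` ([endpoint_params()]), `design`
#'   ([trial_design()]), `n_runs`, `seed` and any driver-specific options.
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  known <- c("params", "n1", "n2min", "n2max", "alpha", "scheme", "tau",
             "n_runs", "seed", "rho_grid", "effect_grid", "test", "rule",
             "out")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("unknown config keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  pr <- raw$params
  params <- if (!is.null(pr$endpoint)) {
    fingolimod_params(pr$endpoint, rho = pr$rho %||% 0)
  } else {
    pk <- setdiff(names(pr), c("mu0", "mu1", "nu0", "nu1", "sigma", "rho"))
    if (length(pk)) {
      stop("unknown keys in `params`: ", paste(pk, collapse = ", "),
           call. = FALSE)
    }
    endpoint_params(mu0 = pr$mu0 %||% 0, mu1 = pr$mu1 %||% 0,
                    nu0 = pr$nu0 %||% 0, nu1 = pr$nu1 %||% 0,
                    sigma = pr$sigma %||% 1, rho = pr$rho %||% 0)
  }
  alpha <- raw$alpha %||% 0.025
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("invalid `alpha`: must be in (0, 1)", call. = FALSE)
  }
  n2max <- raw$n2max %||% Inf
  if (identical(n2max, "Inf")) n2max <- Inf
  if (is.null(raw$n1)) stop("missing required key `n1`", call. = FALSE)
  scheme <- raw$scheme %||% "random_allocation"
  if (scheme == "block" && is.null(raw$tau)) {
    stop("invalid `tau`: required when scheme is \"block\"", call. = FALSE)
  }
  design <- trial_design(n1 = raw$n1, n2min = raw$n2min %||% 0,
                         n2max = n2max, alpha = alpha, scheme = scheme,
                         tau = raw$tau)
  c(list(params = params, design = design,
         n_runs = raw$n_runs %||% 2e5, seed = raw$seed %||% 1L),
    raw[intersect(names(raw), c("rho_grid", "effect_grid", "test",
                                "rule", "out"))])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
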