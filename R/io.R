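# JSON model configuration and delimited trajectory I/O.
#
# A model config is either an explicit network:
#   {"species": ["X"], "initial": {"X": 0},
#    "reactions": [{"products": {"X": 1}, "rate": 10},
#                  {"reactants": {"X": 1}, "rate": 1}]}
# or a named preset with parameter overrides:
#   {"preset": "bursty", "params": {"alpha": 0.0282, "b": 3.46, "tau": 120}}
# Reactions may carry a "propensity" expression over the declared species
# (arithmetic operators, parentheses, numeric literals, pow() and exp()
# only), a "delay" object ({"kind": ..., "value": tau} or
# {"kind": ..., "distribution": "exponential"|"gamma"|"uniform",
#  "params": {...}}), and explicit "s_change"/"s_delay_change" overrides.

model_presets <- function() c("bursty", "refractory", "rna_velocity", "ast", "toggle")

#' Compile a propensity expression against declared species
#'
#' The expression language is deliberately minimal so configs stay portable:
#' numeric literals, the declared species names, `+ - * / ^`, parentheses,
#' and the functions `pow(a, b)` and `exp(a)`. Anything else (including
#' undeclared symbols) is rejected with a diagnostic.
#'
#' @param text expression source, e.g. `"0.4*S + pow(S,2)/(100+pow(S,2))"`.
#' @param species declared species names.
#' @return a propensity `function(x)` over the named count vector.
#' @export
compile_propensity <- function(text, species) {
  e <- tryCatch(str2lang(text), error = function(err)
    stop(sprintf("malformed propensity expression %s: %s",
                 sQuote(text), conditionMessage(err))))
  allowed_fns <- c("+", "-", "*", "/", "^", "(", "pow", "exp")
  walk <- function(node) {
    if (is.numeric(node)) return(invisible())
    if (is.symbol(node)) {
      nm <- as.character(node)
      if (!(nm %in% species))
        stop(sprintf("propensity expression uses undeclared species %s", sQuote(nm)))
      return(invisible())
    }
    if (is.call(node)) {
      fn <- as.character(node[[1]])
      if (!(fn %in% allowed_fns))
        stop(sprintf("propensity expressions may not call %s (allowed: %s)",
                     sQuote(fn), paste(allowed_fns, collapse = " ")))
      for (i in seq_along(node)[-1]) walk(node[[i]])
      return(invisible())
    }
    stop("malformed propensity expression")
  }
  walk(e)
  helpers <- list(pow = function(a, b) a^b, exp = exp)
  fn <- function(x) eval(e, envir = c(as.list(x), helpers))
  attr(fn, "source_text") <- text
  fn
}

parse_delay_config <- function(d) {
  if (is.null(d)) return(delay_spec("none"))
  kind <- d$kind
  if (is.null(kind) || !(kind %in% c("none", "consuming", "completion_only")))
    stop("delay field needs kind = none | consuming | completion_only")
  if (kind == "none") return(delay_spec("none"))
  if (!is.null(d$value)) return(delay_spec(kind, value = d$value))
  if (is.null(d$distribution))
    stop("delayed reaction needs a delay value or distribution")
  pr <- d$params
  sampler <- switch(d$distribution,
    exponential = { rate <- pr$rate; function() rexp(1L, rate) },
    gamma = { sh <- pr$shape; ra <- pr$rate; function() rgamma(1L, sh, ra) },
    uniform = { lo <- pr$min; hi <- pr$max; function() runif(1L, lo, hi) },
    stop(sprintf("unknown delay distribution %s", sQuote(d$distribution))))
  out <- delay_spec(kind, sampler = sampler)
  out$distribution <- d$distribution
  out$params <- pr
  out
}

named_vec <- function(obj) {
  if (is.null(obj) || length(obj) == 0L) return(NULL)
  unlist(obj)
}

#' Parse a JSON model configuration
#'
#' Builds a validated [reaction_network()] and initial state from a JSON
#' file (see the package's `inst/extdata` examples), or instantiates a named
#' preset (`"bursty"`, `"refractory"`, `"rna_velocity"`, `"ast"`,
#' `"toggle"`) with parameter overrides. The `rna_velocity` preset yields a
#' two-phase model; its config carries the phase-1 network plus the model
#' object itself.
#'
#' @param path JSON file path, or a JSON string.
#' @return an object of class `model_config`: list with `network`,
#'   `initial`, and (for presets) `preset`, `params` and possibly `model`.
#' @export
parse_model_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  if (!is.null(cfg$preset)) return(instantiate_preset(cfg))
  if (is.null(cfg$species) || is.null(cfg$reactions))
    stop("model config needs `species` and `reactions` (or a `preset`)")
  species <- as.character(unlist(cfg$species))
  reactions <- lapply(seq_along(cfg$reactions), function(j) {
    rc <- cfg$reactions[[j]]
    bad <- setdiff(names(rc), c("name", "reactants", "products", "rate",
                                "propensity", "delay", "s_change", "s_delay_change"))
    if (length(bad))
      stop(sprintf("reaction %d: unknown config field(s) %s", j,
                   paste(sQuote(bad), collapse = ", ")))
    prop <- NULL
    if (!is.null(rc$propensity)) prop <- compile_propensity(rc$propensity, species)
    r <- reaction(reactants = named_vec(rc$reactants),
                  products = named_vec(rc$products),
                  rate = rc$rate, propensity = prop,
                  delay = parse_delay_config(rc$delay),
                  s_change = named_vec(rc$s_change),
                  s_delay_change = named_vec(rc$s_delay_change),
                  name = rc$name)
    r
  })
  network <- reaction_network(species, reactions)
  initial <- stats::setNames(numeric(length(species)), species)
  if (!is.null(cfg$initial)) {
    iv <- named_vec(cfg$initial)
    unknown <- setdiff(names(iv), species)
    if (length(unknown))
      stop("initial state refers to undeclared species: ",
           paste(unknown, collapse = ", "))
    initial[names(iv)] <- iv
  }
  structure(list(network = network, initial = initial, preset = NULL),
            class = "model_config")
}

instantiate_preset <- function(cfg) {
  preset <- cfg$preset
  if (!(preset %in% model_presets()))
    stop(sprintf("unknown preset %s (available: %s)", sQuote(preset),
                 paste(model_presets(), collapse = ", ")))
  pr <- cfg$params
  arg <- function(nm, default) if (!is.null(pr[[nm]])) pr[[nm]] else default
  model <- NULL
  if (preset == "bursty") {
    network <- bursty_model(alpha = arg("alpha", 0.0282), b = arg("b", 3.46),
                            tau = arg("tau", 120))
  } else if (preset == "refractory") {
    network <- refractory_model(k1 = arg("k1", 0.15), k2 = arg("k2", 0.1),
                                k3 = arg("k3", 0.05), k4 = arg("k4", 10),
                                tau = arg("tau", 1))
  } else if (preset == "rna_velocity") {
    model <- rna_velocity_model(alpha = arg("alpha", 20), beta = arg("beta", 1),
                                gamma = arg("gamma", 0.5),
                                t_switch = arg("t_switch", 50),
                                tau = pr$tau)
    network <- model$phase1
  } else if (preset == "ast") {
    degr <- if (!is.null(pr$k_deg))
      list(k_deg = pr$k_deg, tau_s = arg("tau_s", 1)) else NULL
    network <- ast_model(alpha_s = arg("alpha_s", 0.2), B = arg("B", 6023),
                         degrader = degr)
  } else { # toggle
    network <- toggle_model(alpha = arg("alpha", 50), K = arg("K", 20),
                            n = arg("n", 2), d = arg("d", 1), tau = pr$tau)
  }
  initial <- attr(network, "default_initial")
  if (!is.null(cfg$initial)) {
    iv <- named_vec(cfg$initial)
    unknown <- setdiff(names(iv), network$species)
    if (length(unknown))
      stop("initial state refers to undeclared species: ",
           paste(unknown, collapse = ", "))
    initial[names(iv)] <- iv
  }
  structure(list(network = network, initial = initial, preset = preset,
                 params = pr, model = model),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  if (!is.null(x$preset)) cat(sprintf("Model config (preset %s)\n", sQuote(x$preset)))
  else cat("Model config\n")
  print(x$network)
  cat("initial state:", paste(sprintf("%s = %g", x$network$species, x$initial),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Serialise an explicit model config back to JSON
#'
#' Inverse of [parse_model_config()] for explicit (non-preset) networks:
#' `parse_model_config(write_model_config(cfg, path))` reproduces the same
#' matrices, rates, delays and initial state. Custom propensities are only
#' serialisable when they were compiled from an expression.
#'
#' @param config a `model_config`.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_model_config <- function(config, path) {
  stopifnot(inherits(config, "model_config"))
  net <- config$network
  vec_obj <- function(v) if (is.null(v) || !length(v)) NULL else as.list(v)
  rx <- lapply(seq_len(net$n_reactions), function(j) {
    r <- net$reactions[[j]]
    o <- list()
    if (!is.null(r$name)) o$name <- r$name
    o$reactants <- vec_obj(r$reactants)
    o$products <- vec_obj(r$products)
    if (is.function(r$propensity)) {
      src <- attr(r$propensity, "source_text")
      if (is.null(src))
        stop(sprintf("reaction %d has a closure propensity that cannot be serialised", j))
      o$propensity <- src
    } else {
      o$rate <- r$rate
    }
    if (r$delay$kind != "none") {
      d <- list(kind = r$delay$kind)
      if (!is.null(r$delay$value)) d$value <- r$delay$value
      else {
        if (is.null(r$delay$distribution))
          stop(sprintf("reaction %d has a closure delay sampler that cannot be serialised", j))
        d$distribution <- r$delay$distribution
        d$params <- r$delay$params
      }
      o$delay <- d
    }
    if (!is.null(r$s_change)) o$s_change <- vec_obj(r$s_change)
    if (!is.null(r$s_delay_change)) o$s_delay_change <- vec_obj(r$s_delay_change)
    o[!vapply(o, is.null, logical(1))]
  })
  obj <- list(species = net$species,
              initial = as.list(config$initial),
              reactions = rx)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write trajectories as a delimited long-format table
#'
#' One row per (trajectory, output time): columns `sample`, `time`, then one
#' column per species. Counts are written as integers; the companion
#' [read_trajectories()] round-trips the table bit-exactly.
#'
#' @param ensemble an `ssa_ensemble` or `ssa_trajectory`.
#' @param path output file path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return the path, invisibly.
#' @export
write_trajectories <- function(ensemble, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  if (inherits(ensemble, "ssa_trajectory")) {
    df <- data.frame(sample = 1L, time = ensemble$times)
    counts <- ensemble$states
  } else if (inherits(ensemble, "ssa_ensemble")) {
    nt <- length(ensemble$times)
    df <- data.frame(sample = rep(seq_len(ensemble$n_samples), each = nt),
                     time = rep(ensemble$times, ensemble$n_samples))
    counts <- do.call(rbind, lapply(seq_len(ensemble$n_samples),
                                    function(i) ensemble$states[, , i, drop = FALSE][, , 1]))
    if (length(ensemble$species) == 1L) counts <- matrix(counts, ncol = 1L)
  } else stop("`ensemble` must be an ssa_trajectory or ssa_ensemble")
  counts <- matrix(as.integer(round(counts)), nrow(counts), ncol(counts))
  colnames(counts) <- if (inherits(ensemble, "ssa_trajectory"))
    ensemble$species else ensemble$species
  utils::write.table(cbind(df, counts), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read trajectories written by [write_trajectories()]
#'
#' @param path file path.
#' @param format `"tsv"`, `"csv"`, or `"auto"` (by extension; default).
#' @return an `ssa_ensemble` (or `ssa_trajectory` when the file holds a
#'   single sample).
#' @export
read_trajectories <- function(path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE)
  if (!all(c("sample", "time") %in% names(df)))
    stop("trajectory table needs `sample` and `time` columns")
  species <- setdiff(names(df), c("sample", "time"))
  samples <- sort(unique(df$sample))
  times <- df$time[df$sample == samples[1]]
  nt <- length(times)
  if (length(samples) == 1L) {
    return(structure(list(times = times,
                          states = as.matrix(df[species]),
                          species = species, method = NA_character_,
                          seed = NA_integer_),
                     class = "ssa_trajectory"))
  }
  arr <- array(0, dim = c(nt, length(species), length(samples)),
               dimnames = list(NULL, species, NULL))
  for (i in seq_along(samples)) {
    block <- df[df$sample == samples[i], species, drop = FALSE]
    if (nrow(block) != nt) stop("ragged trajectory table")
    arr[, , i] <- as.matrix(block)
  }
  structure(list(times = times, states = arr, species = species,
                 method = NA_character_, seed = NA_integer_,
                 n_samples = length(samples), pending = NULL),
            class = "ssa_ensemble")
}
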