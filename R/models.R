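# Constructors for the worked models: bursty transcription, the three-state
# refractory promoter, two-phase RNA velocity kinetics, and the four-gene
# lung-cancer adeno-to-squamous transition (AST) network, plus the
# concentration -> molecule-count model conversion they rely on.

#' Volume context for concentration/molecule conversion
#'
#' Relates a concentration `x` (mol/L) to a molecule count `X` through
#' `X = x * V * N_A`. The product `B = V * N_A` is the number of molecules
#' corresponding to one concentration unit; with the conventional rounded
#' Avogadro number 6.023e23 and a cellular-scale volume `V = 1e-20` L,
#' `B = 6023` exactly.
#'
#' @param volume system volume in liters.
#' @param avogadro molecules per mole; default the rounded 6.023e23.
#' @return an object of class `conversion_context` with fields `volume`,
#'   `avogadro` and `B`.
#' @examples
#' conversion_context(1e-20)$B   # 6023
#' @export
conversion_context <- function(volume = 1e-20, avogadro = 6.023e23) {
  if (!is.numeric(volume) || volume <= 0) stop("`volume` must be positive")
  structure(list(volume = volume, avogadro = avogadro, B = volume * avogadro),
            class = "conversion_context")
}

#' @export
print.conversion_context <- function(x, ...) {
  cat(sprintf("<conversion context: V = %g L, N_A = %g, B = V*N_A = %g>\n",
              x$volume, x$avogadro, x$B))
  invisible(x)
}

#' Convert a concentration-based ODE model to molecule counts
#'
#' Gene-network models are often written for concentrations while stochastic
#' simulation is molecule-based. Scaling every species by `B = V * N_A`
#' turns a concentration system `dx/dt = f(x)` into the exactly equivalent
#' molecule-count system `dX/dt = B * f(X / B)`; with `B = 1` the two
#' coincide symbol for symbol.
#'
#' @param rhs concentration-based right-hand side: `function(t, x, ...)`
#'   returning the vector `dx/dt` (deSolve style: a list is also accepted).
#' @param context a [conversion_context()], or a bare positive number `B`.
#' @return an object of class `molecule_model`: list with `rhs` (a deSolve
#'   compatible `function(t, X, parms)` on molecule counts) and `B`.
#' @examples
#' decay <- function(t, x, parms) -0.5 * x
#' mol <- convert_concentration_model(decay, conversion_context(1e-20))
#' mol$rhs(0, 6023, NULL)  # -3011.5 molecules per time unit
#' @export
convert_concentration_model <- function(rhs, context) {
  B <- if (inherits(context, "conversion_context")) context$B else context
  if (!is.numeric(B) || length(B) != 1L || B <= 0)
    stop("conversion requires a positive scaling factor B")
  if (!is.function(rhs)) stop("`rhs` must be a function(t, x, ...)")
  mol_rhs <- function(t, X, parms) {
    d <- rhs(t, X / B, parms)
    if (is.list(d)) d <- d[[1]]
    list(B * d)
  }
  structure(list(rhs = mol_rhs, B = B), class = "molecule_model")
}

#' Bursty transcription model
#'
#' Nascent mRNA is produced in geometrically distributed bursts (mean size
#' `b`, burst frequency `alpha`) and every molecule of a burst is degraded
#' exactly `tau` time units after the burst. Bursts are encoded as a
#' truncated family of reactions 0 -> k*M, k = 1..k_max, with propensity
#' `alpha * b^k / (1+b)^(k+1)` (a mean-`b` geometric burst-size law); the
#' family is truncated where the residual geometric tail mass drops below
#' `tail_mass`. Each firing applies +k immediately and schedules the matching
#' -k at `t + tau`, so the stationary copy number is the batch M/D/infinity
#' value with mean `alpha * b * tau`.
#'
#' @param alpha burst frequency (bursts per time unit).
#' @param b mean burst size (molecules).
#' @param tau deterministic molecule lifetime.
#' @param tail_mass truncation bound on the residual burst-size mass.
#' @return a [reaction_network()] with one species `M` and a
#'   `default_initial` attribute of `c(M = 0)`.
#' @examples
#' net <- bursty_model(0.0282, 3.46, 120)
#' sum(propensities(net, c(M = 0)))   # ~ alpha * b / (1 + b)
#' @export
bursty_model <- function(alpha = 0.0282, b = 3.46, tau = 120,
                         tail_mass = 1e-6) {
  if (alpha <= 0 || b <= 0 || tau < 0) stop("invalid Bursty parameters")
  r <- b / (1 + b)
  k_max <- max(1L, ceiling(log(tail_mass) / log(r)))
  reactions <- lapply(seq_len(k_max), function(k)
    reaction(rate = alpha * b^k / (1 + b)^(k + 1),
             delay = delay_spec("consuming", value = tau),
             s_change = c(M = k), s_delay_change = c(M = -k),
             name = sprintf("burst_%d", k)))
  net <- reaction_network("M", reactions)
  attr(net, "default_initial") <- c(M = 0)
  net
}

#' Three-state refractory promoter model
#'
#' The gene cycles through states G0 -> G1 -> G2 -> G0 (rates `k1`, `k2`,
#' `k3`); nascent mRNA is produced only in G2 at rate `k4`, and each
#' transcript is degraded exactly `tau` after production. The long refractory
#' residence in G0/G1 makes the mRNA marginal bimodal with a large mass at
#' zero; the stationary mean is `k4 * tau * P(G2)` with
#' `P(G2) = (1/k3) / (1/k1 + 1/k2 + 1/k3)`.
#'
#' @param k1,k2,k3 gene-state switching rates of the cycle.
#' @param k4 transcription rate in state G2.
#' @param tau deterministic transcript lifetime.
#' @return a [reaction_network()] on species G0, G1, G2, M with
#'   `default_initial` `c(G0 = 1, G1 = 0, G2 = 0, M = 0)`.
#' @export
refractory_model <- function(k1 = 0.15, k2 = 0.1, k3 = 0.05, k4 = 10,
                             tau = 1) {
  if (any(c(k1, k2, k3) <= 0) || k4 < 0 || tau < 0)
    stop("invalid Refractory parameters")
  reactions <- list(
    reaction(reactants = c(G0 = 1), products = c(G1 = 1), rate = k1, name = "G0->G1"),
    reaction(reactants = c(G1 = 1), products = c(G2 = 1), rate = k2, name = "G1->G2"),
    reaction(reactants = c(G2 = 1), products = c(G0 = 1), rate = k3, name = "G2->G0"),
    reaction(reactants = c(G2 = 1), rate = k4,
             delay = delay_spec("consuming", value = tau),
             s_change = c(M = 1), s_delay_change = c(M = -1),
             name = "transcription"))
  net <- reaction_network(c("G0", "G1", "G2", "M"), reactions)
  attr(net, "default_initial") <- c(G0 = 1, G1 = 0, G2 = 0, M = 0)
  net
}

#' Two-phase RNA velocity model
#'
#' Unspliced mRNA U is transcribed at rate `alpha`, spliced into mature mRNA
#' S at rate `beta`, and S is degraded at rate `gamma` -- optionally as a
#' delayed (completion-only) reaction with lag `tau`. Transcription switches
#' off at `t_switch`: phase 1 (up-regulation) relaxes toward the means
#' `E[U] = alpha/beta`, `E[S] = alpha/gamma`; phase 2 (down-regulation,
#' `alpha = 0`) decays back to the origin, tracing the characteristic two-arc
#' U-S phase portrait. Use [simulate_rna_velocity()] to run both phases with
#' the pending-completion queue carried across the switch.
#'
#' @param alpha transcription rate in phase 1.
#' @param beta splicing rate.
#' @param gamma degradation rate of S.
#' @param t_switch time at which transcription stops.
#' @param tau optional degradation delay; NULL for the Markovian model.
#' @return an object of class `rna_velocity_model`.
#' @export
rna_velocity_model <- function(alpha = 20, beta = 1, gamma = 0.5,
                               t_switch = 50, tau = NULL) {
  if (any(c(alpha, beta, gamma) < 0) || t_switch <= 0)
    stop("invalid RNA velocity parameters")
  deg <- if (is.null(tau)) {
    reaction(reactants = c(S = 1), rate = gamma, name = "degradation")
  } else {
    reaction(reactants = c(S = 1), rate = gamma,
             delay = delay_spec("completion_only", value = tau),
             name = "degradation")
  }
  make_net <- function(a) {
    rs <- list(reaction(products = c(U = 1), rate = a, name = "transcription"),
               reaction(reactants = c(U = 1), products = c(S = 1), rate = beta,
                        name = "splicing"),
               deg)
    net <- reaction_network(c("U", "S"), rs)
    attr(net, "default_initial") <- c(U = 0, S = 0)
    net
  }
  structure(list(phase1 = make_net(alpha), phase2 = make_net(0),
                 alpha = alpha, beta = beta, gamma = gamma,
                 t_switch = t_switch, tau = tau),
            class = "rna_velocity_model")
}

#' @export
print.rna_velocity_model <- function(x, ...) {
  cat(sprintf("RNA velocity model: alpha = %g (off after t = %g), beta = %g, gamma = %g%s\n",
              x$alpha, x$t_switch, x$beta, x$gamma,
              if (is.null(x$tau)) "" else sprintf(", degradation delay tau = %g", x$tau)))
  invisible(x)
}

#' Simulate the two-phase RNA velocity model
#'
#' Runs phase 1 (transcription on) to `t_switch`, then continues each
#' trajectory with transcription off until `t_final`, preserving the state
#' and -- in the delayed variant -- the pending-completion queue across the
#' switch, so degradations scheduled in phase 1 still complete in phase 2.
#'
#' @param model an [rna_velocity_model()].
#' @param t_final total horizon (> `t_switch`).
#' @param times output grid over `[0, t_final]`; default step 0.5.
#' @param n_samples number of trajectories.
#' @param seed integer seed (replicate i uses `seed + i - 1`).
#' @param method simulation engine; `"auto"` picks direct or delay_rejection.
#' @return `ssa_trajectory` or `ssa_ensemble` spanning both phases.
#' @export
simulate_rna_velocity <- function(model, t_final = 100, times = NULL,
                                  n_samples = 1L, seed = NULL,
                                  method = "auto") {
  stopifnot(inherits(model, "rna_velocity_model"))
  if (t_final <= model$t_switch) stop("`t_final` must exceed t_switch")
  if (is.null(times)) times <- seq(0, t_final, by = 0.5)
  if (is.unsorted(times) || any(times < 0) || any(times > t_final))
    stop("`times` must be sorted within [0, t_final]")
  delayed <- !is.null(model$tau)
  if (identical(method, "auto")) method <- if (delayed) "delay_rejection" else "direct"
  method <- match.arg(method, ssa_methods())
  if (delayed && !delay_capable(method)) method <- upgrade_method(method)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
  seed <- as.integer(seed)
  plan1 <- compile_network(model$phase1)
  plan2 <- compile_network(model$phase2)
  ts <- model$t_switch
  t1 <- times[times <= ts]
  t2 <- times[times > ts] - ts
  engine <- switch(method,
                   direct = engine_direct,
                   first_reaction = engine_first_reaction,
                   mnr = engine_mnr,
                   delay_rejection = engine_delay_rejection,
                   delay_direct = engine_delay_direct,
                   delay_mnr = engine_delay_mnr)
  x0 <- c(U = 0, S = 0)
  one <- function(i) {
    set.seed(seed + i - 1L)
    if (delay_capable(method)) {
      q <- event_queue(2L)
      # phase 1, with the switch time itself on the grid so the hand-over
      # state is recorded exactly
      st1 <- engine(plan1, x0, ts, c(t1, ts), q)
      x_sw <- st1[nrow(st1), ]
      st1 <- st1[seq_along(t1), , drop = FALSE]
      shift_queue_times(q, -ts)
      st2 <- engine(plan2, x_sw, t_final - ts, t2, q)
      rbind(st1, st2)
    } else {
      st1 <- engine(plan1, x0, ts, c(t1, ts))
      x_sw <- st1[nrow(st1), ]
      st1 <- st1[seq_along(t1), , drop = FALSE]
      st2 <- engine(plan2, x_sw, t_final - ts, t2)
      rbind(st1, st2)
    }
  }
  if (n_samples == 1L) {
    st <- one(1L)
    structure(list(times = times,
                   states = `colnames<-`(st, c("U", "S")),
                   species = c("U", "S"), method = method, seed = seed),
              class = "ssa_trajectory")
  } else {
    arr <- array(0, dim = c(length(times), 2L, n_samples),
                 dimnames = list(NULL, c("U", "S"), NULL))
    for (i in seq_len(n_samples)) arr[, , i] <- one(i)
    structure(list(times = times, states = arr, species = c("U", "S"),
                   method = method, seed = seed, n_samples = as.integer(n_samples),
                   pending = NULL),
              class = "ssa_ensemble")
  }
}

# translate all pending completion times (used when restarting the clock)
shift_queue_times <- function(q, dt) {
  if (queue_size(q) > 0L)
    q$times[q$head:q$tail] <- q$times[q$head:q$tail] + dt
  invisible(q)
}

#' Default parameters of the AST regulatory network
#'
#' The four-gene lung-cancer adeno-to-squamous transition circuit couples
#' the adenocarcinoma factors FOXA2 (F) and NKX2-1 (N) with the squamous
#' factors P63 (P) and SOX2 (S) through mutual Hill-type repression, SOX2
#' self-activation and linear degradation. `alpha_s`, the basal SOX2
#' production strength, is the control parameter of the adeno-to-squamous
#' transition and is therefore supplied separately to [ast_model()] and
#' [ast_ode_rhs()].
#'
#' @param alpha_f,alpha_n,alpha_p production strengths of F, N and P.
#' @param beta_s SOX2 self-activation strength.
#' @param a1,a2,a3,a4,a5,a6,a7,a8,a9 Hill interaction coefficients.
#' @param d_f,d_n,d_p,d_s degradation rates.
#' @return named list of parameters.
#' @export
ast_parameters <- function(alpha_f = 2.9, alpha_n = 1, alpha_p = 1,
                           beta_s = 1.3,
                           a1 = 1, a2 = 1, a3 = 0.8, a4 = 2, a5 = 0.8,
                           a6 = 1, a7 = 2, a8 = 1, a9 = 1,
                           d_f = 1, d_n = 1, d_p = 1, d_s = 0.4) {
  p <- list(alpha_f = alpha_f, alpha_n = alpha_n, alpha_p = alpha_p,
            beta_s = beta_s, a1 = a1, a2 = a2, a3 = a3, a4 = a4, a5 = a5,
            a6 = a6, a7 = a7, a8 = a8, a9 = a9,
            d_f = d_f, d_n = d_n, d_p = d_p, d_s = d_s)
  if (any(unlist(p) < 0)) stop("AST parameters must be nonnegative")
  p
}

# concentration-based AST right-hand side (deSolve style)
ast_ode_rhs_concentration <- function(alpha_s, params = ast_parameters()) {
  p <- params
  function(t, x, parms) {
    F <- x[1]; N <- x[2]; P <- x[3]; S <- x[4]
    dF <- p$alpha_f / (1 + p$a1 * P^2 + p$a2 * S^2) - p$d_f * F
    dN <- p$alpha_n * (1 + F^2) / (1 + p$a3 * F^2 + p$a4 * S^2) - p$d_n * N
    dP <- p$alpha_p * (1 + S^2) / (1 + p$a5 * S^2 + p$a6 * N^2) - p$d_p * P
    dS <- p$beta_s * S^2 / (p$a7^2 + S^2) +
      alpha_s / (1 + p$a8 * F^2 + p$a9 * N^2) - p$d_s * S
    list(c(dF, dN, dP, dS))
  }
}

#' Deterministic AST network equations
#'
#' Right-hand side of the AST ODE system, either in concentration units
#' (`B = 1`) or converted to molecule counts via
#' [convert_concentration_model()] (every species scaled by `B`). An
#' effective SOX2 degrader can be added as an extra linear degradation term
#' `-k_deg * S`, the deterministic skeleton of the delayed degradation
#' reaction of [ast_model()].
#'
#' @param alpha_s basal SOX2 production strength (control parameter).
#' @param params an [ast_parameters()] list.
#' @param B molecule scaling factor `V * N_A`; default 6023.
#' @param k_deg extra SOX2 degradation rate (degrader), default 0.
#' @return `function(t, y, parms)` for [deSolve::ode()], with species order
#'   F, N, P, S.
#' @export
ast_ode_rhs <- function(alpha_s, params = ast_parameters(), B = 6023,
                        k_deg = 0) {
  conc <- ast_ode_rhs_concentration(alpha_s, params)
  mol <- convert_concentration_model(conc, B)$rhs
  if (k_deg == 0) return(mol)
  function(t, y, parms) {
    d <- mol(t, y, parms)[[1]]
    d[4] <- d[4] - k_deg * y[4]
    list(d)
  }
}

#' Stochastic AST network
#'
#' Molecule-count reaction network of the adeno-to-squamous transition
#' circuit: per species one production reaction whose (custom, Hill-type)
#' propensity is the molecule-based production term of the converted ODEs,
#' and one linear mass-action degradation. SOX2's self-activation and basal
#' production are combined into its single production propensity
#' `B*beta_s*S^2 / (B^2*a7^2 + S^2) + B^3*alpha_s / (B^2 + a8*F^2 + a9*N^2)`.
#'
#' With `degrader` given, one further reaction models a SOX2-targeting
#' degrader: propensity `k_deg * S`, with the removal of one S molecule
#' deferred (completion-only) by `tau_s`.
#'
#' @param alpha_s basal SOX2 production strength.
#' @param params an [ast_parameters()] list.
#' @param B molecule scaling factor; default 6023 (V = 1e-20 L).
#' @param degrader NULL, or `list(k_deg = , tau_s = )`.
#' @return a [reaction_network()] on species F, N, P, S with a
#'   `default_initial` attribute at the origin.
#' @examples
#' net <- ast_model(alpha_s = 0.05)
#' propensities(net, c(F = 0, N = 0, P = 0, S = 0))[1]  # B * alpha_f
#' @export
ast_model <- function(alpha_s, params = ast_parameters(), B = 6023,
                      degrader = NULL) {
  if (!is.numeric(alpha_s) || alpha_s < 0) stop("`alpha_s` must be nonnegative")
  if (B <= 0) stop("`B` must be positive")
  p <- params
  B2 <- B^2; B3 <- B^3
  prod_F <- function(x) B3 * p$alpha_f / (B2 + p$a1 * x[[3L]]^2 + p$a2 * x[[4L]]^2)
  prod_N <- function(x) B * p$alpha_n * (B2 + x[[1L]]^2) /
    (B2 + p$a3 * x[[1L]]^2 + p$a4 * x[[4L]]^2)
  prod_P <- function(x) B * p$alpha_p * (B2 + x[[4L]]^2) /
    (B2 + p$a5 * x[[4L]]^2 + p$a6 * x[[2L]]^2)
  prod_S <- function(x) B * p$beta_s * x[[4L]]^2 / (B2 * p$a7^2 + x[[4L]]^2) +
    B3 * alpha_s / (B2 + p$a8 * x[[1L]]^2 + p$a9 * x[[2L]]^2)
  reactions <- list(
    reaction(products = c(F = 1), propensity = prod_F, name = "F_production"),
    reaction(reactants = c(F = 1), rate = p$d_f, name = "F_degradation"),
    reaction(products = c(N = 1), propensity = prod_N, name = "N_production"),
    reaction(reactants = c(N = 1), rate = p$d_n, name = "N_degradation"),
    reaction(products = c(P = 1), propensity = prod_P, name = "P_production"),
    reaction(reactants = c(P = 1), rate = p$d_p, name = "P_degradation"),
    reaction(products = c(S = 1), propensity = prod_S, name = "S_production"),
    reaction(reactants = c(S = 1), rate = p$d_s, name = "S_degradation"))
  if (!is.null(degrader)) {
    if (!is.list(degrader) || is.null(degrader$k_deg) || is.null(degrader$tau_s))
      stop("`degrader` must be list(k_deg = , tau_s = )")
    reactions <- c(reactions, list(
      reaction(reactants = c(S = 1), rate = degrader$k_deg,
               delay = delay_spec("completion_only", value = degrader$tau_s),
               name = "S_degrader")))
  }
  net <- reaction_network(c("F", "N", "P", "S"), reactions)
  attr(net, "default_initial") <- c(F = 0, N = 0, P = 0, S = 0)
  net
}

#' Generic two-gene toggle switch (test model)
#'
#' Mutual repression of two genes with Hill-type production
#' `alpha / (1 + (other/K)^n)` and linear degradation; bistable at the
#' default parameters. Provided as a simple self-contained test network,
#' optionally with delayed (consuming) production.
#'
#' @param alpha maximal production rate.
#' @param K repression threshold (molecules).
#' @param n Hill coefficient.
#' @param d degradation rate.
#' @param tau optional production delay.
#' @return a [reaction_network()] on species A, B.
#' @export
toggle_model <- function(alpha = 50, K = 20, n = 2, d = 1, tau = NULL) {
  if (any(c(alpha, K, n, d) <= 0)) stop("invalid toggle parameters")
  prod_A <- function(x) alpha / (1 + (x[[2L]] / K)^n)
  prod_B <- function(x) alpha / (1 + (x[[1L]] / K)^n)
  del <- if (is.null(tau)) delay_spec("none") else delay_spec("consuming", value = tau)
  mk <- function(pfun, target) {
    if (is.null(tau))
      reaction(products = stats::setNames(1, target), propensity = pfun,
               name = paste0(target, "_production"))
    else
      reaction(propensity = pfun, delay = del,
               s_delay_change = stats::setNames(1, target),
               name = paste0(target, "_production"))
  }
  net <- reaction_network(c("A", "B"), list(
    mk(prod_A, "A"),
    reaction(reactants = c(A = 1), rate = d, name = "A_degradation"),
    mk(prod_B, "B"),
    reaction(reactants = c(B = 1), rate = d, name = "B_degradation")))
  attr(net, "default_initial") <- c(A = 0, B = 0)
  net
}
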