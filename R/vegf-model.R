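AVOGADRO <- 6.02214076e23

#' Convert a per-cell receptor level to a compartment concentration
#'
#' `level` receptors on each of `cells` cells dissolved in `volume` liters:
#' `pM = level * cells / (N_A * volume) * 1e12`.
#'
#' @param level Receptors per cell (>= 0).
#' @param cells Number of cells bearing the receptor (>= 0).
#' @param volume Compartment fluid volume in liters (> 0).
#' @return Concentration in pM.
#' @export
receptors_per_cell_to_concentration <- function(level, cells, volume) {
  stopifnot(all(level >= 0), all(cells >= 0))
  if (any(volume <= 0)) stop("volume must be > 0")
  level * cells / (AVOGADRO * volume) * 1e12
}

#' Default parameterization of the three-compartment VEGF model
#'
#' All rates are order-of-magnitude literature-plausible values for human
#' VEGF-A and a bevacizumab-like antibody; absolute concentrations predicted
#' with them are illustrative, while the model structure (compartments,
#' species, binding, transport) and the anchored constants (control levels
#' of 1100 VEGFR1/cell and 700 VEGFR2/cell, a 50/50 luminal/abluminal
#' receptor split on endothelial cells, a t = 0 bolus and a 3-week horizon)
#' are fixed. Kd(VEGFR1) = koff/kon = 10 pM < Kd(VEGFR2) = 100 pM encodes
#' VEGFR1's higher VEGF affinity.
#'
#' @return Nested list of model constants (units in the element names or
#'   documented here: volumes L, cell counts, kon 1/(pM s), koff and other
#'   first-order rates 1/s, secretion pM/s, flows L/s, GAG site
#'   concentrations pM).
#' @export
default_model_config <- function() {
  list(
    volumes = c(normal = 10, blood = 5, diseased = 1e-3),
    cells = c(healthy_ec = 1e11, myocyte = 2e11, tumor_ec = 1e8, tumor_cell = 1e9),
    # ligand-receptor kinetics per receptor type
    kon = c(VEGFR1 = 3e-5, VEGFR2 = 1e-5, NRP1 = 1e-5),
    koff = c(VEGFR1 = 3e-4, VEGFR2 = 1e-3, NRP1 = 3e-3),
    k_int = 2.8e-4,               # receptor internalization, 1/s
    # anti-VEGF (drug) binding: Kd = 50 pM
    kon_drug = 1e-5, koff_drug = 5e-4,
    # VEGF secretion, pM/s into the compartment fluid
    secretion = c(normal = 1e-2, blood = 1e-3, diseased = 0.4),
    clearance_vegf = 1.9e-4,      # from blood, 1/s
    clearance_drug = 4e-7,        # antibody and complex, from blood, 1/s
    # transvascular permeability flows, L/s (blood <-> tissue)
    perm_flow = c(normal = 1e-5, diseased = 2e-7),
    # lymphatic drainage flows, L/s (tissue -> blood)
    lymph_flow = c(normal = 2e-6, diseased = 1e-7),
    macro_perm_factor = 0.3,      # antibody/complex permeability relative to VEGF
    # GAG (matrix) binding sites in tissue compartments
    gag_sites = c(normal = 1e4, diseased = 1e4),
    kon_gag = 1e-6, koff_gag = 1e-2,
    # control whole-cell surface receptor levels, receptors/cell
    control_levels = list(
      healthy_ec = c(VEGFR1 = 1100, VEGFR2 = 700, NRP1 = 40000),
      tumor_ec   = c(VEGFR1 = 1100, VEGFR2 = 700, NRP1 = 40000),
      tumor_cell = c(VEGFR1 = 1100, VEGFR2 = 700),
      myocyte    = c(VEGFR1 = 1100, VEGFR2 = 700)
    )
  )
}

# Surface layout: endothelial cells straddle the vessel wall, so their
# luminal surface sits in blood and their abluminal surface in the tissue
# they line; tumor cells and myocytes are wholly interstitial.
surface_table <- function() {
  data.frame(
    surface = c("ec_lum", "ec_ab", "tec_lum", "tec_ab", "tumor", "myo"),
    cell_type = c("healthy_ec", "healthy_ec", "tumor_ec", "tumor_ec",
                  "tumor_cell", "myocyte"),
    compartment = c("blood", "normal", "blood", "diseased", "diseased", "normal"),
    stringsAsFactors = FALSE
  )
}

#' Build the three-compartment VEGF/anti-VEGF model
#'
#' Compartments: normal tissue, blood, diseased tissue. Species: free VEGF,
#' free anti-VEGF and their complex in every compartment; GAG-bound VEGF in
#' the tissue compartments; and, for every (cell surface, receptor) pair,
#' free and VEGF-occupied surface receptor. Endothelial surfaces are split
#' luminal (blood) / abluminal (adjacent tissue); receptors are pre-dimerized
#' homodimers, i.e. one binding site per counted receptor. Receptor turnover
#' is insertion at rate `s_R` and internalization of free and bound receptor
#' at `k_int`, so the total surface level relaxes to `s_R / k_int`
#' independently of ligand.
#'
#' @param config A configuration list as from [default_model_config()].
#' @return Object of class `vegf_model`.
#' @export
vegf_model <- function(config = default_model_config()) {
  stopifnot(all(unlist(config$volumes) > 0),
            config$k_int >= 0, all(config$kon >= 0), all(config$koff >= 0))
  surf <- surface_table()
  rows <- list()
  for (i in seq_len(nrow(surf))) {
    ct <- surf$cell_type[i]
    levels <- config$control_levels[[ct]]
    # endothelial whole-cell levels split 50/50 across the two surfaces
    split <- if (ct %in% c("healthy_ec", "tumor_ec")) 0.5 else 1
    for (rec in names(levels)) {
      rows[[length(rows) + 1]] <- data.frame(
        surface = surf$surface[i], cell_type = ct,
        compartment = surf$compartment[i], receptor = rec,
        level = levels[[rec]] * split, stringsAsFactors = FALSE
      )
    }
  }
  pairs <- do.call(rbind, rows)
  pairs$pair <- paste(pairs$surface, pairs$receptor, sep = ".")
  pairs$cells <- config$cells[pairs$cell_type]
  pairs$kon <- config$kon[pairs$receptor]
  pairs$koff <- config$koff[pairs$receptor]
  pairs$conc <- receptors_per_cell_to_concentration(
    pairs$level, pairs$cells, config$volumes[pairs$compartment])
  pairs$s <- pairs$conc * config$k_int   # insertion rate, pM/s
  model <- structure(list(config = config, pairs = pairs), class = "vegf_model")
  model
}

#' @export
print.vegf_model <- function(x, ...) {
  cat(sprintf("vegf_model: 3 compartments, %d receptor surfaces\n", nrow(x$pairs)))
  print(x$pairs[, c("pair", "compartment", "level", "conc", "s")], row.names = FALSE)
  invisible(x)
}

#' Update a surface receptor level from an extracted population statistic
#'
#' Injects a representative receptors/cell value into the model. For
#' endothelial cell types the whole-cell level is split equally between the
#' luminal and abluminal surfaces (e.g. 1100 VEGFR1/cell becomes 550 per
#' surface); tumor cells and myocytes carry the whole level on their single
#' interstitial surface. The insertion rate is rescaled as
#' `s_R = level_per_surface * k_int` so the drug-free steady-state surface
#' level equals the requested level.
#'
#' @param model A [vegf_model()].
#' @param cell_type One of `"healthy_ec"`, `"tumor_ec"`, `"tumor_cell"`,
#'   `"myocyte"`.
#' @param receptor One of `"VEGFR1"`, `"VEGFR2"`, `"NRP1"`.
#' @param whole_cell_level Total receptors/cell (>= 0).
#' @return The updated model.
#' @export
apply_receptor_update <- function(model, cell_type, receptor, whole_cell_level) {
  stopifnot(inherits(model, "vegf_model"), whole_cell_level >= 0)
  cell_type <- match.arg(cell_type, c("healthy_ec", "tumor_ec", "tumor_cell", "myocyte"))
  receptor <- match.arg(receptor, c("VEGFR1", "VEGFR2", "NRP1"))
  sel <- model$pairs$cell_type == cell_type & model$pairs$receptor == receptor
  if (!any(sel)) stop(sprintf("%s carries no %s in this model", cell_type, receptor))
  split <- if (cell_type %in% c("healthy_ec", "tumor_ec")) 0.5 else 1
  model$pairs$level[sel] <- whole_cell_level * split
  model$pairs$conc[sel] <- receptors_per_cell_to_concentration(
    model$pairs$level[sel], model$pairs$cells[sel],
    model$config$volumes[model$pairs$compartment[sel]])
  model$pairs$s[sel] <- model$pairs$conc[sel] * model$config$k_int
  model
}

#' An anti-VEGF dose schedule
#'
#' @param amount Bolus amount added to blood free anti-VEGF at t = 0 (pM).
#' @param horizon Simulation horizon in seconds after injection (default 3
#'   weeks).
#' @return Object of class `dose_schedule`.
#' @export
dose_schedule <- function(amount = 1e4, horizon = 3 * 7 * 86400) {
  stopifnot(amount >= 0, horizon > 0)
  structure(list(amount = amount, horizon = horizon), class = "dose_schedule")
}

COMPARTMENTS <- c("normal", "blood", "diseased")

state_template <- function(model) {
  nm <- c(paste0("V.", COMPARTMENTS), paste0("A.", COMPARTMENTS),
          paste0("C.", COMPARTMENTS), "GB.normal", "GB.diseased",
          paste0("R.", model$pairs$pair), paste0("RV.", model$pairs$pair))
  stats::setNames(numeric(length(nm)), nm)
}

# Build the derivative closure once per model: index bookkeeping is hoisted
# out of the inner loop.
model_derivative <- function(model) {
  cfg <- model$config
  pairs <- model$pairs
  np <- nrow(pairs)
  tmpl <- state_template(model)
  nm <- names(tmpl)
  iV <- match(paste0("V.", COMPARTMENTS), nm)
  iA <- match(paste0("A.", COMPARTMENTS), nm)
  iC <- match(paste0("C.", COMPARTMENTS), nm)
  iGB <- match(c("GB.normal", "GB.diseased"), nm)
  iR <- match(paste0("R.", pairs$pair), nm)
  iRV <- match(paste0("RV.", pairs$pair), nm)
  comp_of_pair <- match(pairs$compartment, COMPARTMENTS)
  M <- matrix(0, 3, np)             # compartment x pair incidence
  M[cbind(comp_of_pair, seq_len(np))] <- 1
  vol <- cfg$volumes[COMPARTMENTS]
  q <- cfg$secretion[COMPARTMENTS]
  kon <- pairs$kon; koff <- pairs$koff; s <- pairs$s; kint <- cfg$k_int
  gag_M <- cfg$gag_sites[c("normal", "diseased")]
  transport <- function(x, perm_factor = 1) {
    # x = concentrations (normal, blood, diseased); returns dx from
    # permeability (blood <-> tissue), lymph (tissue -> blood)
    jp_n <- perm_factor * cfg$perm_flow[["normal"]] * (x[2] - x[1])
    jp_d <- perm_factor * cfg$perm_flow[["diseased"]] * (x[2] - x[3])
    jl_n <- cfg$lymph_flow[["normal"]] * x[1]
    jl_d <- cfg$lymph_flow[["diseased"]] * x[3]
    c((jp_n - jl_n) / vol[1],
      (-jp_n - jp_d + jl_n + jl_d) / vol[2],
      (jp_d - jl_d) / vol[3])
  }
  force(s)
  function(y, s_override = NULL) {
    sr <- if (is.null(s_override)) s else s_override
    V <- y[iV]; A <- y[iA]; Cc <- y[iC]; GB <- y[iGB]
    R <- y[iR]; RV <- y[iRV]
    dy <- numeric(length(y))
    # receptor binding (per pair) and VEGF consumption per compartment
    Vp <- V[comp_of_pair]
    bind <- kon * Vp * R - koff * RV
    dy[iR] <- sr - kint * R - bind
    dy[iRV] <- bind - kint * RV
    cons <- as.numeric(M %*% bind)
    # drug binding in each compartment
    db <- cfg$kon_drug * V * A - cfg$koff_drug * Cc
    # GAG association in tissue compartments
    g <- cfg$kon_gag * V[c(1, 3)] * (gag_M - GB) - cfg$koff_gag * GB
    dy[iGB] <- g
    dV <- q - cons - db + transport(V)
    dV[1] <- dV[1] - g[1]
    dV[3] <- dV[3] - g[2]
    dV[2] <- dV[2] - cfg$clearance_vegf * V[2]
    dA <- -db + transport(A, cfg$macro_perm_factor)
    dA[2] <- dA[2] - cfg$clearance_drug * A[2]
    dC <- db + transport(Cc, cfg$macro_perm_factor)
    dC[2] <- dC[2] - cfg$clearance_drug * Cc[2]
    dy[iV] <- dV; dy[iA] <- dA; dy[iC] <- dC
    dy
  }
}

#' Simulate the compartment model under an anti-VEGF bolus
#'
#' Procedure: (1) the drug-free steady state is found by long integration
#' followed by Newton refinement and verified (`|dy/dt|` below 1e-9
#' relative); (2) the bolus is added to blood free anti-VEGF at t = 0;
#' (3) the system is integrated to the horizon with the stiff Rosenbrock
#' solver. All binding is mass-action.
#'
#' @param model A [vegf_model()].
#' @param dose A [dose_schedule()].
#' @param init Optional named initial state (skips the steady-state search;
#'   used for controlled experiments). Must match [state names of] the model.
#' @param steady_state If `FALSE`, start from `init` (or zeros) without the
#'   steady-state search.
#' @param n_out Number of output times.
#' @param rtol,atol Solver tolerances.
#' @return Object of class `simulation_result`: `times` (s), `states`
#'   (matrix, one row per time), `ss` (pre-injection steady state),
#'   `free_vegf` (data.frame time x compartment), `dose`.
#' @export
simulate_model <- function(model, dose = dose_schedule(), init = NULL,
                           steady_state = TRUE, n_out = 101,
                           rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(model, "vegf_model"), inherits(dose, "dose_schedule"))
  f <- model_derivative(model)
  tmpl <- state_template(model)
  if (steady_state) {
    y0 <- tmpl
    y0[paste0("R.", model$pairs$pair)] <-
      if (model$config$k_int > 0) model$pairs$s / model$config$k_int else 0
    if (!is.null(init)) y0[names(init)] <- init
    run <- ode_rosenbrock(f, y0, times = c(0, 10^seq(2, log10(4e6), length.out = 20)),
                          rtol = rtol, atol = atol)
    y_ss <- newton_steady_state(f, run[nrow(run), ])
    resid <- max(abs(f(y_ss)) / pmax(abs(y_ss), 1))
    if (resid > 1e-9) {
      stop(sprintf("steady state not verified: relative residual %.3g", resid))
    }
    y_ss[y_ss < 0 & y_ss > -atol * 100] <- 0
    if (any(y_ss < 0)) stop("negative steady state beyond tolerance")
  } else {
    y_ss <- tmpl
    if (!is.null(init)) y_ss[names(init)] <- init
  }
  y1 <- y_ss
  y1["A.blood"] <- y1["A.blood"] + dose$amount
  times <- seq(0, dose$horizon, length.out = n_out)
  states <- ode_rosenbrock(f, y1, times, rtol = rtol, atol = atol)
  neg <- states < 0
  if (any(states[neg] < -1e-4 * max(abs(states)))) {
    stop("negative concentrations beyond tolerance during integration")
  }
  states[neg] <- 0
  free_vegf <- data.frame(
    time = times,
    normal = states[, "V.normal"],
    blood = states[, "V.blood"],
    diseased = states[, "V.diseased"]
  )
  structure(
    list(times = times, states = states, ss = y_ss, free_vegf = free_vegf,
         dose = dose),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  last <- nrow(x$free_vegf)
  cat(sprintf("simulation_result: bolus %.4g pM, horizon %.3g d\n",
              x$dose$amount, x$dose$horizon / 86400))
  for (cm in COMPARTMENTS) {
    cat(sprintf("  %-8s free VEGF: %.4g -> %.4g pM\n",
                cm, x$ss[paste0("V.", cm)], x$free_vegf[[cm]][last]))
  }
  invisible(x)
}

#' Fold change in free VEGF relative to the pre-injection steady state
#'
#' `FC = (C(horizon) - C(0-)) / C(0-)` per compartment, where `C(0-)` is the
#' pre-injection steady state; an increase after injection is positive, a
#' decrease negative. When a control simulation is supplied the normalized
#' fold change `FC / FC_control` is reported too (the control normalized to
#' itself is 1).
#'
#' @param sim A [simulate_model()] result.
#' @param control_sim Optional control-run result on the same horizon.
#' @return Object of class `fold_change_report`: data.frame with
#'   `compartment`, `pre`, `post`, `fc` and (with a control) `fc_normalized`.
#' @export
fold_change <- function(sim, control_sim = NULL) {
  stopifnot(inherits(sim, "simulation_result"))
  last <- nrow(sim$free_vegf)
  pre <- vapply(COMPARTMENTS, function(cm) sim$ss[[paste0("V.", cm)]], numeric(1))
  post <- vapply(COMPARTMENTS, function(cm) sim$free_vegf[[cm]][last], numeric(1))
  if (any(pre == 0)) stop("pre-injection free VEGF is 0; fold change undefined")
  report <- data.frame(compartment = COMPARTMENTS, pre = pre, post = post,
                       fc = (post - pre) / pre, row.names = NULL)
  if (!is.null(control_sim)) {
    stopifnot(inherits(control_sim, "simulation_result"))
    if (abs(control_sim$dose$horizon - sim$dose$horizon) > 1e-6) {
      stop("control simulation must share the horizon")
    }
    ctrl <- fold_change(control_sim)
    report$fc_normalized <- report$fc / ctrl$fc
  }
  class(report) <- c("fold_change_report", "data.frame")
  report
}

#' Parameter sensitivity scan
#'
#' Runs one simulation and fold-change computation per grid point while
#' varying one quantity: the membrane insertion rate of a (surface,
#' receptor) pair (receptors/cell/s), its steady-state surface receptor
#' level (receptors/cell, per surface), or any scalar rate in the model
#' configuration (e.g. `"clearance_vegf"`).
#'
#' @param model A [vegf_model()].
#' @param parameter `"insertion_rate"`, `"receptor_level"` or the name of a
#'   scalar configuration entry.
#' @param grid Nonnegative parameter values to scan.
#' @param pair For the receptor parameters, the pair id (e.g.
#'   `"tec_ab.VEGFR1"`; see `model$pairs$pair`).
#' @param dose A [dose_schedule()].
#' @param control_sim Optional control simulation for normalized fold
#'   changes.
#' @return data.frame with one row per (grid point, compartment): `value`,
#'   `compartment`, `pre`, `post`, `fc` (and `fc_normalized` with a
#'   control).
#' @export
sensitivity_scan <- function(model, parameter, grid, pair = NULL,
                             dose = dose_schedule(), control_sim = NULL) {
  stopifnot(inherits(model, "vegf_model"), all(grid >= 0))
  rows <- list()
  for (v in grid) {
    m <- model
    if (parameter %in% c("insertion_rate", "receptor_level")) {
      if (is.null(pair) || !pair %in% m$pairs$pair) {
        stop("`pair` must name a receptor surface in model$pairs$pair")
      }
      sel <- m$pairs$pair == pair
      level <- if (parameter == "receptor_level") v else v / m$config$k_int
      m$pairs$level[sel] <- level
      m$pairs$conc[sel] <- receptors_per_cell_to_concentration(
        level, m$pairs$cells[sel], m$config$volumes[m$pairs$compartment[sel]])
      m$pairs$s[sel] <- m$pairs$conc[sel] * m$config$k_int
    } else {
      if (!parameter %in% names(m$config) || length(m$config[[parameter]]) != 1) {
        stop(sprintf("unknown scalar parameter '%s'", parameter))
      }
      m$config[[parameter]] <- v
    }
    sim <- simulate_model(m, dose)
    fc <- fold_change(sim, control_sim)
    fc$value <- v
    rows[[length(rows) + 1]] <- fc
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(out) <- NULL
  out
}
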