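# Configuration, serialization and fixtures.  Formats are plain text:
# YAML configs, tab-separated rasters/synapse tables with a JSON sidecar
# for group membership.  Times are ms, conductances nS, currents pA,
# voltages mV in every file.

CONFIG_SECTIONS <- c("network", "neuron", "plasticity", "protocol")

default_protocol_settings <- function() {
  list(balance_duration = 50000, eta_start = 0.005, eta_end = 1e-5,
       n_epochs = 10, dt = 0.1, g_max = 3, cue_fraction = 1,
       cue_jitter = 0, trial_window = 200, rate_ceiling = 100)
}

#' Load a hierarchical configuration file
#'
#' Reads a YAML file with optional sections `network`, `neuron`,
#' `plasticity`, `protocol`; omitted keys take the package defaults (the
#' reference parameter set: 20,000/5,000 neurons, p_rand = 0.01, 10 groups
#' of M = 500, g_E = 0.1 nS, g_I = 0.4 nS, 2 ms delays, target rate 5
#' spikes/s).  Unknown sections or keys are rejected.
#'
#' @param path YAML file; an empty or missing-section file yields defaults.
#' @return List with `network` ([network_spec()]), `neuron`
#'   ([neuron_params()]), `plasticity` ([plasticity_params()]), `protocol`
#'   (plain list of protocol settings).
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), CONFIG_SECTIONS)
  if (length(unknown)) {
    stop("load_config: unknown section(s): ", paste(unknown, collapse = ", "))
  }
  take <- function(section, fn, defaults) {
    given <- raw[[section]]
    if (is.null(given)) given <- list()
    bad <- setdiff(names(given), names(defaults))
    if (length(bad)) {
      stop("load_config: unknown key(s) in '", section, "': ",
           paste(bad, collapse = ", "))
    }
    args <- utils::modifyList(defaults, given)
    if (is.null(fn)) args else do.call(fn, args)
  }
  spec_defaults <- list(N_E = 20000, N_I = 5000, p_rand = 0.01, M = 500,
                        n_groups = 10, p_rc = 0.06, p_ff = 0.06,
                        wiring_mode = "feedforward", g_E = 0.1, g_ff = 0.1,
                        g_I = 0.4, g_EI_init = 0.4, delay = 2, seed = 1L)
  np_defaults <- formals(neuron_params)
  np_defaults <- lapply(np_defaults, eval)
  pp_defaults <- list(tau_STDP = 20, eta = 0.005, rho_0 = 5, g_min = 0)
  list(network = take("network", network_spec, spec_defaults),
       neuron = take("neuron", neuron_params, np_defaults),
       plasticity = take("plasticity", plasticity_params, pp_defaults),
       protocol = take("protocol", NULL, default_protocol_settings()))
}

#' Write / read a spike raster
#'
#' Two-column tab-separated text (`time_ms`, `neuron`); round-trips exactly.
#'
#' @param raster data frame with `time_ms`, `neuron`.
#' @param path file path.
#' @return `read_raster` returns the data frame.
#' @export
write_raster <- function(raster, path) {
  df <- data.frame(time_ms = format(raster$time_ms, digits = 17,
                                    trim = TRUE, scientific = FALSE),
                   neuron = raster$neuron)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("numeric", "integer"))
  names(df) <- c("time_ms", "neuron")
  df
}

#' Write / read a connectivity set
#'
#' The synapse table goes to `<path>` as tab-separated text with the stable
#' column order `pre, post, class, g_nS, delay_ms`; the spec, group
#' membership and dummy ids go to the JSON sidecar `<path>.json`.
#'
#' @param conn a `connectivity_set`.
#' @param path base file path.
#' @return `read_connectivity` returns the `connectivity_set`.
#' @export
write_connectivity <- function(conn, path) {
  s <- conn$synapses[, c("pre", "post", "class", "g_nS", "delay_ms")]
  s$g_nS <- format(s$g_nS, digits = 17, trim = TRUE, scientific = FALSE)
  write.table(s, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(spec = unclass(conn$spec),
               groups = lapply(conn$groups, function(g) {
                 list(E = g$E, I = g$I)
               }),
               dummy = conn$dummy)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  s <- read.table(path, header = TRUE, sep = "\t",
                  colClasses = c("integer", "integer", "character",
                                 "numeric", "numeric"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec_args <- side$spec
  spec <- do.call(network_spec, spec_args[names(spec_args) != ""])
  groups <- list()
  if (length(side$groups)) {
    groups <- lapply(seq_len(nrow_safe(side$groups)), function(k) {
      g <- extract_group(side$groups, k)
      list(E = as.integer(g$E), I = as.integer(g$I))
    })
  }
  new_connectivity(s, spec, groups = groups,
                   dummy = as.integer(side$dummy))
}

nrow_safe <- function(groups) {
  if (is.data.frame(groups)) nrow(groups) else length(groups)
}

extract_group <- function(groups, k) {
  if (is.data.frame(groups)) {
    list(E = groups$E[[k]], I = groups$I[[k]])
  } else {
    groups[[k]]
  }
}

#' Write a metrics table
#'
#' Long-format tab-separated table; the column set is stable:
#' any of `p_ff`, `p_rc`, `seed`, `trial`, `quality`, `chain_length`,
#' `rate`, `cv`, `synchrony` that are present are written in that order,
#' followed by any extra columns.
#'
#' @param df metrics data frame.
#' @param path file path.
#' @export
write_metrics <- function(df, path) {
  lead <- intersect(c("p_ff", "p_rc", "seed", "trial", "quality",
                      "chain_length", "rate", "cv", "synchrony"),
                    names(df))
  df <- df[, c(lead, setdiff(names(df), lead)), drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  read.table(path, header = TRUE, sep = "\t")
}

#' Deterministic miniature fixtures
#'
#' Named, seed-reproducible objects for testing and examples:
#' \describe{
#'   \item{`two-neuron-delay`}{two excitatory neurons with one 1 nS synapse,
#'     for delay-contract checks.}
#'   \item{`tiny-balanced`}{a size-scaled random network (`N_E` = 400)
#'     balanced for 10 s.}
#'   \item{`clean-replay-raster`}{synthetic raster of a clean 10-group
#'     replay (one spike per neuron, 2 ms dispersion, 8 ms group spacing)
#'     with a silent dummy group; scores quality 1.}
#'   \item{`burst-raster`}{same layout but group 2 fires a tight double
#'     volley; scores 0 with reason `burst`.}
#' }
#'
#' @param name fixture name.
#' @param seed fixture seed.
#' @return The fixture: a `connectivity_set`, a `balance_result`, or a
#'   list with `raster`, `conn` (rasters come with a matching miniature
#'   connectivity for scoring).
#' @export
make_fixture <- function(name = c("two-neuron-delay", "tiny-balanced",
                                  "clean-replay-raster", "burst-raster"),
                         seed = 1L) {
  name <- match.arg(name)
  if (name == "two-neuron-delay") {
    spec <- network_spec(N_E = 2, N_I = 0, p_rand = 0, M = 0, n_groups = 0,
                         seed = seed)
    conn <- build_background(spec)
    conn$synapses <- data.frame(pre = 1L, post = 2L, class = "EE",
                                g_nS = 1, delay_ms = spec$delay)
    return(conn)
  }
  if (name == "tiny-balanced") {
    base <- network_spec(N_E = 20000, N_I = 5000, M = 4, n_groups = 0,
                         seed = seed)
    spec <- scale_network(base, gamma = 0.02)$spec
    conn <- build_background(spec)
    return(balance_phase(conn, duration = 10000))
  }
  # synthetic replay rasters over a miniature sequence layout
  n_groups <- 10L
  M <- 52L
  spec <- network_spec(N_E = n_groups * M + M, N_I = 0, p_rand = 0, M = M,
                       n_groups = n_groups, seed = seed)
  conn <- build_background(spec)
  conn$groups <- lapply(seq_len(n_groups), function(k) {
    list(E = ((k - 1L) * M + 1L):(k * M), I = integer(0))
  })
  conn$dummy <- (n_groups * M + 1L):(n_groups * M + M)
  raster <- with_substream(seed, "fixture-raster", {
    pieces <- lapply(seq_len(n_groups), function(k) {
      centre <- 50 + (k - 1L) * 8
      data.frame(time_ms = rnorm(M, centre, 2), neuron = conn$groups[[k]]$E)
    })
    df <- do.call(rbind, pieces)
    if (name == "burst-raster") {
      g2 <- conn$groups[[2L]]$E
      extra <- data.frame(
        time_ms = rep(58 + seq(0, 0.5, length.out = M), 2),
        neuron = c(g2, g2))
      df <- rbind(df, extra)
    }
    df[order(df$time_ms), ]
  })
  rownames(raster) <- NULL
  list(raster = raster, conn = conn)
}
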