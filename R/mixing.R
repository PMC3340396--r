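#' Propagate tributary endmembers downstream by conservative mixing
#'
#' Walks the station graph in topological order. At every confluence the
#' concentration of each constituent (aCDOM340, tripton, SRP) is the
#' discharge-weighted mean of the inflows; along an edge without inflow the
#' water is unchanged (default), or decays first-order at rate
#' `config$decay` per edge if configured. Discharge accumulates downstream;
#' a node whose out-flow splits across several edges divides its discharge
#' equally among them.
#'
#' With `decay = 0` the mass flux (concentration x discharge) of every
#' constituent is conserved across every confluence.
#'
#' @param graph A [river_graph()] from [generate_network()].
#' @param config A [river_config()] supplying origin discharges and
#'   endmember concentrations.
#' @return Tibble with one row per station: `station`, `discharge` (m^3 s^-1),
#'   `acdom` (m^-1), `tripton` (mg L^-1), `srp` (ug L^-1).
#' @export
#' @examples
#' cfg <- river_config(n_transects = 3, stations_per_transect = 2, seed = 1)
#' mix_downstream(generate_network(cfg), cfg)
mix_downstream <- function(graph, config) {
  config <- validate_river_config(config)
  ig <- as_igraph(graph)
  ord <- names(igraph::topo_sort(ig, mode = "out"))
  edges <- graph$edges
  outdeg <- table(edges$parent)

  # per-origin discharge and endmember concentrations
  origins <- origin_ids(graph)
  em <- list()
  Q0 <- setNames(numeric(length(origins)), origins)
  for (o in origins) {
    if (o == "O_main") {
      Q0[o] <- config$main_discharge
      em[[o]] <- unlist(config$main_endmember[c("acdom", "tripton", "srp")])
    } else {
      nm <- sub("^O_", "", o)
      tr <- config$tributaries
      row <- tr[tr$name == nm, , drop = FALSE]
      if (is.null(tr) || nrow(row) != 1)
        rl_abort(paste("no endmember configured for origin", o), "config_error")
      Q0[o] <- row$discharge
      em[[o]] <- c(acdom = row$acdom, tripton = row$tripton, srp = row$srp)
    }
  }

  decay_fac <- exp(-config$decay)
  Q <- Q0
  conc <- em
  for (node in ord) {
    if (node %in% origins) next
    inflow <- edges[edges$child == node, , drop = FALSE]
    q_in <- numeric(nrow(inflow))
    c_in <- matrix(0, nrow(inflow), 3,
                   dimnames = list(NULL, c("acdom", "tripton", "srp")))
    for (i in seq_len(nrow(inflow))) {
      p <- inflow$parent[i]
      q_in[i] <- Q[[p]] / as.numeric(outdeg[[p]])
      c_in[i, ] <- conc[[p]][c("acdom", "tripton", "srp")] * decay_fac
    }
    qt <- sum(q_in)
    if (qt <= 0)
      rl_abort(paste("zero total discharge at node", node), "arithmetic_error")
    Q[[node]] <- qt
    conc[[node]] <- colSums(c_in * q_in) / qt
  }

  st <- station_ids(graph)
  tibble(
    station = st,
    discharge = unname(unlist(Q[st])),
    acdom = unname(vapply(conc[st], `[[`, numeric(1), "acdom")),
    tripton = unname(vapply(conc[st], `[[`, numeric(1), "tripton")),
    srp = unname(vapply(conc[st], `[[`, numeric(1), "srp"))
  )
}
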