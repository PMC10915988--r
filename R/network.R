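# run expr with a private RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.cortical_layers <- function() c("L2/3", "L4", "L5", "L6")

.population_names <- function() {
  c(paste0(rep(.cortical_layers(), each = 2), c("_PY", "_IN")),
    "TC_FO", "NRT_FO", "TC_HO", "NRT_HO")
}

#' Default corticothalamic network configuration
#'
#' Six sectors: four cortical layers (each split into two subsectors) plus a
#' first-order and a higher-order thalamic sector, each holding relay (TC) and
#' reticular (NRT) neurons. At full scale each cortical layer has 100
#' excitatory and 50 FS inhibitory neurons (split over its two subsectors) and
#' each thalamic population has 75 neurons, for 900 neurons in total. The desk
#' scale divides all counts by 5 (180 neurons) and shrinks projection radii
#' accordingly; structural invariants are preserved.
#'
#' The configuration carries per-subsector excitatory compositions, the
#' projection table (source, target, receptor, radius, weight, latency range)
#' and per-population state parameters (background-drive rate/weight,
#' potassium-leak scaling per behavioural state, GABA-B receptor densities,
#' tonic GABA-A baseline). Weights are conductance-density increments at the
#' target (mS/cm^2); GABA-B weights scale the transmitter pulse feeding the
#' G-protein cascade.
#'
#' @param scale `"full"` (900 neurons) or `"desk"` (180 neurons).
#' @return A list of class `swd_network_config`.
#' @export
default_network_config <- function(scale = c("full", "desk")) {
  scale <- match.arg(scale)
  k <- if (scale == "desk") 5 else 1

  # per-subsector excitatory composition (full scale; counts divide by k)
  comp_full <- list(
    "L2/3" = c(RS = 30, EF = 10, IB = 10),
    "L4"   = c(RS = 35, EF = 15),
    "L5"   = c(RS = 20, IB = 15, RIB = 10, ND = 5),
    "L6"   = c(RS = 25, IB = 15, EF = 10)
  )
  comp <- lapply(comp_full, function(x) {
    y <- round(x / k)
    # keep per-subsector excitatory total at 50/k
    y[1] <- 50 / k - sum(y[-1])
    y
  })
  fs_per_subsector <- 25 / k
  thal_n <- 75 / k

  proj <- function(src, tgt, receptor, radius, weight, lat_lo, lat_hi) {
    data.frame(source = src, target = tgt, receptor = receptor,
               radius = max(1L, as.integer(round(radius / k))),
               weight = weight, lat_lo = lat_lo, lat_hi = lat_hi,
               stringsAsFactors = FALSE)
  }
  P <- list()
  for (L in .cortical_layers()) {
    py <- paste0(L, "_PY"); fs <- paste0(L, "_IN")
    P <- c(P, list(
      proj(py, py, "AMPA", 30, 0.012, 1, 3),
      proj(py, fs, "AMPA", 30, 0.020, 1, 2),
      proj(fs, py, "GABAA", 30, 0.030, 1, 2),
      proj(fs, py, "GABAB", 30, 0.500, 1, 2),
      proj(fs, fs, "GABAA", 30, 0.010, 1, 2)
    ))
  }
  P <- c(P, list(
    proj("L4_PY", "L2/3_PY", "AMPA", 30, 0.010, 1, 3),
    proj("L2/3_PY", "L5_PY", "AMPA", 30, 0.010, 1, 3),
    proj("L5_PY", "L6_PY", "AMPA", 30, 0.008, 1, 3),
    proj("L6_PY", "L4_PY", "AMPA", 30, 0.006, 1, 3),
    # thalamocortical
    proj("TC_FO", "L4_PY", "AMPA", 35, 0.030, 13, 17),
    proj("TC_FO", "L4_IN", "AMPA", 35, 0.040, 13, 17),
    proj("TC_FO", "NRT_FO", "AMPA", 25, 0.015, 2, 4),
    proj("TC_HO", "L5_PY", "AMPA", 35, 0.040, 13, 17),
    proj("TC_HO", "L2/3_PY", "AMPA", 35, 0.020, 13, 17),
    proj("TC_HO", "NRT_HO", "AMPA", 25, 0.015, 2, 4),
    # corticothalamic
    proj("L6_PY", "TC_FO", "AMPA", 35, 0.008, 7, 9),
    proj("L6_PY", "NRT_FO", "AMPA", 35, 0.012, 6, 8),
    proj("L5_PY", "TC_HO", "AMPA", 35, 0.008, 7, 9),
    proj("L5_PY", "NRT_HO", "AMPA", 35, 0.012, 6, 8),
    # intrathalamic
    proj("NRT_FO", "TC_FO", "GABAA", 25, 0.030, 2, 4),
    proj("NRT_FO", "TC_FO", "GABAB", 25, 0.600, 2, 4),
    proj("NRT_HO", "TC_HO", "GABAA", 25, 0.030, 2, 4),
    proj("NRT_HO", "TC_HO", "GABAB", 25, 0.800, 2, 4),
    proj("NRT_FO", "NRT_FO", "GABAA", 25, 0.015, 1, 3),
    proj("NRT_HO", "NRT_HO", "GABAA", 25, 0.015, 1, 3)
  ))
  projections <- do.call(rbind, P)

  # per-population state parameters: background Poisson drive and the
  # behavioural-state potassium-leak scaling (the sleep-wake-transition state
  # raises g_KL, lowering input resistance mostly in thalamic neurons)
  pops <- .population_names()
  is_py <- grepl("_PY$", pops); is_in <- grepl("_IN$", pops)
  is_tc <- grepl("^TC", pops); is_nrt <- grepl("^NRT", pops)
  state_par <- data.frame(
    population = pops,
    noise_rate = ifelse(is_py | is_in, 300, ifelse(is_tc, 200, 100)),
    noise_w = ifelse(is_py, 0.005, ifelse(is_in, 0.005,
                     ifelse(is_tc, 0.004, 0.002))),
    g_KL_wake = ifelse(is_tc, 0.15, ifelse(is_nrt, 0.2, 1)),
    g_KL_transition = ifelse(pops == "TC_FO", 0.55,
                      ifelse(pops == "TC_HO", 1,
                      ifelse(is_nrt, 1, 1.5))),
    g_GABAb_max = ifelse(is_py, 0.06, ifelse(is_in, 0.04,
                  ifelse(pops == "TC_FO", 0.08,
                  ifelse(pops == "TC_HO", 0.25, 0)))),
    stringsAsFactors = FALSE
  )

  structure(list(scale = scale, k = k, composition = comp,
                 fs_per_subsector = fs_per_subsector, thal_n = thal_n,
                 projections = projections, state = state_par),
            class = "swd_network_config")
}

#' Place neurons of one subsector
#'
#' Cell types are assigned to row positions pseudo-randomly (seeded); ids are
#' sequential from `start_id`.
#'
#' @param composition Named integer vector of cell-type counts.
#' @param seed Integer seed; the same seed reproduces the same placement.
#' @param start_id First neuron id.
#' @return Data frame with `id`, `cell_type`, `position` (0-based row index).
#' @export
place_neurons <- function(composition, seed, start_id = 1L) {
  stopifnot(all(composition > 0))
  types <- rep(names(composition), composition)
  n <- length(types)
  perm <- .with_seed(seed, sample.int(n))
  df <- data.frame(id = seq.int(start_id, length.out = n),
                   cell_type = types[order(perm)],
                   position = seq_len(n) - 1L,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop("duplicate neuron ids")
  df
}

#' Realize one topographic projection
#'
#' Source and target rows are aligned by linear index rescaling; each source
#' contacts the targets within `radius` positions of its matching region
#' (at most `2 * radius + 1` contacts), never itself, and at most once per
#' target pair. Latencies are drawn uniformly from the configured range with
#' a seeded generator.
#'
#' @param source,target Data frames with `id` and `position` columns.
#' @param receptor Receptor kind.
#' @param radius Projection radius in target-row positions (>= 1).
#' @param weight Connection weight.
#' @param lat_range Length-2 numeric, latency range (ms).
#' @param seed Integer seed.
#' @return Data frame of connection rows
#'   (`pre_id`, `post_id`, `receptor`, `weight`, `latency_ms`).
#' @export
build_projection <- function(source, target, receptor, radius, weight,
                             lat_range = c(1, 3), seed = 1L) {
  stopifnot(nrow(source) > 0, nrow(target) > 0, radius >= 1)
  ns <- nrow(source); nt <- nrow(target)
  if (radius > nt) {
    warning("projection radius exceeds target extent; clipping")
    radius <- nt
  }
  src_pos <- source$position
  ctr <- if (ns == 1) rep(round((nt - 1) / 2), 1)
         else round(src_pos / max(src_pos) * (nt - 1))
  pre <- integer(0); post <- integer(0)
  for (i in seq_len(ns)) {
    lo <- max(0, ctr[i] - radius); hi <- min(nt - 1, ctr[i] + radius)
    tgt <- target$id[target$position >= lo & target$position <= hi]
    tgt <- tgt[tgt != source$id[i]]
    pre <- c(pre, rep(source$id[i], length(tgt)))
    post <- c(post, tgt)
  }
  lat <- .with_seed(seed, runif(length(pre), lat_range[1], lat_range[2]))
  data.frame(pre_id = pre, post_id = post, receptor = receptor,
             weight = weight, latency_ms = lat, stringsAsFactors = FALSE)
}

#' Build the default corticothalamic network
#'
#' Constructs the six-sector network: per-layer cortical populations (PY and
#' FS rows, two subsectors each), thalamic relay and reticular populations,
#' and all configured topographic projections, including the reciprocal
#' TC-NRT loops of both thalamic sectors.
#'
#' @param config `swd_network_config` from [default_network_config()].
#' @param seed Integer seed (placement and latencies are deterministic in it).
#' @return Object of class `swd_network`: list with `neurons` (id, population,
#'   sector, subsector, cell_type, position, flags), `connections` (the
#'   connection table) and the echoed `config` and `seed`.
#' @export
build_default_network <- function(config = default_network_config(),
                                  seed = 1L) {
  stopifnot(inherits(config, "swd_network_config"))
  neurons <- list()
  next_id <- 1L
  sub_seed <- seed

  add_pop <- function(pop, sector, comp_list) {
    # comp_list: list of per-subsector compositions
    out <- list()
    for (si in seq_along(comp_list)) {
      sub_seed <<- sub_seed + 1L
      pl <- place_neurons(comp_list[[si]], seed = sub_seed,
                          start_id = next_id)
      next_id <<- next_id + nrow(pl)
      pl$subsector <- paste0(pop, letters[si])
      out[[si]] <- pl
    }
    df <- do.call(rbind, out)
    df$position <- seq_len(nrow(df)) - 1L  # contiguous row across subsectors
    df$population <- pop
    df$sector <- sector
    df
  }

  for (L in .cortical_layers()) {
    comp <- config$composition[[L]]
    neurons[[paste0(L, "_PY")]] <-
      add_pop(paste0(L, "_PY"), L, list(comp, comp))
    neurons[[paste0(L, "_IN")]] <-
      add_pop(paste0(L, "_IN"), L,
              list(c(FS = config$fs_per_subsector),
                   c(FS = config$fs_per_subsector)))
  }
  for (pop in c("TC_FO", "NRT_FO", "TC_HO", "NRT_HO")) {
    sector <- if (grepl("FO", pop)) "thal_FO" else "thal_HO"
    neurons[[pop]] <- add_pop(pop, sector,
                              list(setNames(config$thal_n,
                                            sub("_.*", "", pop))))
    neurons[[pop]]$cell_type <- pop  # TC/NRT classes carry their order label
  }
  nd <- do.call(rbind, neurons)
  rownames(nd) <- NULL
  nd$is_cortical <- nd$sector %in% .cortical_layers()
  nd$is_excitatory <- !grepl("_IN$|^NRT", nd$population)

  conns <- list()
  pr <- config$projections
  for (i in seq_len(nrow(pr))) {
    src <- nd[nd$population == pr$source[i], c("id", "position")]
    tgt <- nd[nd$population == pr$target[i], c("id", "position")]
    if (nrow(src) == 0 || nrow(tgt) == 0)
      stop("projection references missing population: ",
           pr$source[i], " -> ", pr$target[i])
    conns[[i]] <- build_projection(src, tgt, pr$receptor[i], pr$radius[i],
                                   pr$weight[i],
                                   c(pr$lat_lo[i], pr$lat_hi[i]),
                                   seed = seed * 1000L + i)
  }
  ct <- do.call(rbind, conns)
  # pair uniqueness within a receptor kind
  key <- paste(ct$pre_id, ct$post_id, ct$receptor)
  ct <- ct[!duplicated(key), ]
  rownames(ct) <- NULL

  net <- structure(list(neurons = nd, connections = ct, config = config,
                        seed = seed), class = "swd_network")
  net
}

#' @export
print.swd_network <- function(x, ...) {
  cat("<swd_network> ", nrow(x$neurons), " neurons (",
      x$config$scale, " scale), ", nrow(x$connections),
      " connections\n", sep = "")
  tab <- table(x$neurons$population)
  cat("  populations:",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Substitute strongly intrinsically bursting (SIB) cells
#'
#' Replaces a fraction of the IB-class cells in the named layers with the SIB
#' parameter set; connectivity is unchanged.
#'
#' @param network `swd_network`.
#' @param layers Subset of `c("L5", "L6")`.
#' @param fraction Fraction of IB cells to substitute, in \[0, 1\].
#' @param seed Integer seed for selecting the substituted cells.
#' @return Modified `swd_network`.
#' @export
substitute_sib <- function(network, layers = "L5", fraction = 1, seed = 1L) {
  stopifnot(inherits(network, "swd_network"), length(layers) > 0)
  if (!all(layers %in% c("L5", "L6"))) stop("layers must be in {L5, L6}")
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  nd <- network$neurons
  cand <- which(nd$cell_type == "IB" &
                nd$population %in% paste0(layers, "_PY"))
  n_sub <- round(fraction * length(cand))
  if (n_sub > 0) {
    pick <- .with_seed(seed, sample(cand, n_sub))
    nd$cell_type[pick] <- "SIB"
  }
  network$neurons <- nd
  network
}

#' Connection table of a network
#' @param network `swd_network`.
#' @return Data frame (`pre_id`, `post_id`, `receptor`, `weight`,
#'   `latency_ms`).
#' @export
connection_table <- function(network) network$connections

#' Export the connection table as CSV
#' @param network `swd_network`.
#' @param path Output file.
#' @export
write_connection_table <- function(network, path) {
  write.csv(network$connections, path, row.names = FALSE)
  invisible(path)
}

#' Reproducibility hash of a network
#'
#' 32-bit FNV-1a hash over neuron and connection tables; identical
#' (config, seed) pairs produce identical hashes.
#'
#' @param network `swd_network`.
#' @return Hash as hexadecimal string.
#' @export
network_hash <- function(network) {
  txt <- paste(
    paste(network$neurons$id, network$neurons$cell_type,
          network$neurons$population, network$neurons$position,
          collapse = ";"),
    paste(network$connections$pre_id, network$connections$post_id,
          network$connections$receptor,
          signif(network$connections$weight, 8),
          signif(network$connections$latency_ms, 8), collapse = ";"),
    sep = "|")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte, keeping h as a double below 2^32
    h <- (h %/% 256) * 256 + bitwXor(as.integer(h %% 256), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
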