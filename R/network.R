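#' Cell kinds of the cerebellar microcircuit
#'
#' The model contains five populations per hemisphere: mossy fibers (MF),
#' Golgi cells (GO), granule cells (GC), basket/stellate cells (BC) and
#' Purkinje cells (PC).
#'
#' @return character vector of the five kind codes
#' @export
cell_kinds <- function() c("MF", "GO", "GC", "BC", "PC")

#' Default per-hemisphere population counts
#'
#' The knockdown experiments keep 257 MFs, 27 GOs, 267 BCs and a single PC
#' per hemisphere constant while the initial GC population is 4000.
#'
#' @return named integer vector over [cell_kinds()]
#' @export
default_counts <- function() {
  c(MF = 257L, GO = 27L, GC = 4000L, BC = 267L, PC = 1L)
}

#' Anatomical whole-network population counts
#'
#' The anatomical reference configuration of the model (convergence/divergence
#' table): 562 MFs, 56 GOs, 8192 GCs, 548 BCs, 30 PCs. Provided as an
#' alternative to [default_counts()]; the two configurations are not a simple
#' factor of each other and both are supported.
#'
#' @return named integer vector over [cell_kinds()]
#' @export
anatomical_counts <- function() {
  c(MF = 562L, GO = 56L, GC = 8192L, BC = 548L, PC = 30L)
}

# Projection table: source/target kinds, anatomical convergence (fan-in per
# target cell) and synaptic sign. PF denotes the parallel-fiber axon of a GC,
# so all pf_* projections originate in the GC population.
projection_table <- function() {
  data.frame(
    proj   = c("mf_gc", "go_gc", "mf_go", "pf_go", "bc_go",
               "pf_bc", "pc_bc", "pf_pc", "bc_pc"),
    src    = c("MF", "GO", "MF", "GC", "BC", "GC", "PC", "GC", "BC"),
    dst    = c("GC", "GC", "GO", "GO", "GO", "BC", "BC", "PC", "PC"),
    fan_in = c(4L, 4L, 66L, 1639L, 28L, 41L, 3L, 1024L, 110L),
    sign   = c("exc", "inh", "exc", "exc", "inh",
               "exc", "inh", "exc", "inh"),
    stringsAsFactors = FALSE
  )
}

#' Fan-in table for a given population configuration
#'
#' Starts from the anatomical convergence ratios (MF->GC 4, GO->GC 4,
#' MF->GO 66, PF->GO 1639, BC->GO 28, PF->BC 41, PC->BC 3, PF->PC 1024,
#' BC->PC 110) and caps each fan-in at the available source-population size.
#' When a hemisphere carries a single PC (the experimental configuration),
#' PF->PC becomes all-to-one: the lone PC receives every parallel fiber,
#' which is what makes graded GC knockdown with drive-preserving
#' renormalization well defined.
#'
#' @param counts named population counts as from [default_counts()]
#' @return data.frame with columns proj, src, dst, fan_in, sign
#' @export
fan_in_table <- function(counts = default_counts()) {
  tab <- projection_table()
  src_n <- counts[tab$src]
  if (counts[["PC"]] == 1L) {
    tab$fan_in[tab$proj == "pf_pc"] <- counts[["GC"]]
  }
  tab$fan_in <- pmin(tab$fan_in, as.integer(src_n))
  tab
}

#' Place a population uniformly at random in the tissue cube
#'
#' Each hemisphere occupies a cube of edge length 100 um; every neuron of
#' every population is dropped uniformly at random inside it.
#'
#' @param kind one of [cell_kinds()]
#' @param count number of cells (>= 0)
#' @param edge_um cube edge length in micrometers
#' @param seed integer seed for the placement stream
#' @return an object of class `population_layout`: list(kind, count,
#'   positions) where positions is a `count x 3` matrix in `[0, edge_um]`
#' @export
place_neurons <- function(kind, count, edge_um = 100, seed = 1L) {
  kind <- match.arg(kind, cell_kinds())
  if (length(count) != 1L || is.na(count) || count < 0) {
    stop("configuration error: cell count for ", kind, " must be >= 0")
  }
  if (edge_um <= 0) stop("configuration error: edge_um must be > 0")
  count <- as.integer(count)
  pos <- with_stream(seed, matrix(runif(3L * count, 0, edge_um), ncol = 3L))
  colnames(pos) <- c("x", "y", "z")
  structure(list(kind = kind, count = count, positions = pos,
                 edge_um = edge_um),
            class = "population_layout")
}

#' Wire targets to their nearest sources
#'
#' Connects every target cell to the `fan_in` distinct source cells at the
#' smallest Euclidean distance in the 3D tissue cube (nearest-neighbour
#' rule). Distance ties are broken in favour of the lowest source index so a
#' rebuild under the same seeds is bit-identical.
#'
#' @param targets,sources `population_layout` objects
#' @param fan_in number of afferents per target cell
#' @param proj projection label used in error messages
#' @return integer matrix `n_targets x fan_in` of source indices
#' @export
wire_nearest_neighbor <- function(targets, sources, fan_in, proj = "proj") {
  if (fan_in > sources$count) {
    stop("construction error in projection ", proj, ": fan_in ", fan_in,
         " exceeds source count ", sources$count)
  }
  if (targets$count == 0L) {
    return(matrix(integer(0), nrow = 0L, ncol = fan_in))
  }
  tp <- targets$positions
  sp <- sources$positions
  # squared-distance matrix targets x sources
  d2 <- outer(rowSums(tp^2), rep(1, nrow(sp))) +
    outer(rep(1, nrow(tp)), rowSums(sp^2)) - 2 * tcrossprod(tp, sp)
  conn <- matrix(0L, nrow = targets$count, ncol = fan_in)
  idx_all <- seq_len(sources$count)
  for (i in seq_len(targets$count)) {
    ord <- order(d2[i, ], idx_all)   # stable: ties -> lowest source index
    conn[i, ] <- ord[seq_len(fan_in)]
  }
  conn
}

# Per-target normalizer d: inverse of the number of same-sign (excitatory or
# inhibitory) inputs of the cell, pooled across all projections of that sign
# terminating on the cell's population.
normalizers <- function(fan_tab) {
  d <- list()
  for (dst in unique(fan_tab$dst)) {
    for (sg in c("exc", "inh")) {
      n_in <- sum(fan_tab$fan_in[fan_tab$dst == dst & fan_tab$sign == sg])
      if (n_in > 0) d[[paste(dst, sg, sep = ".")]] <- 1 / n_in
    }
  }
  d
}

#' Initialize synaptic weights
#'
#' Raw magnitudes are drawn from a normal distribution (mean 0.9, sd 0.1)
#' truncated by resampling to `[0.8, 1]`, then multiplied by the cell-wise
#' normalizer d, the inverse of the number of inputs of the same nature
#' (excitatory or inhibitory) of the target cell. Inhibitory weights are
#' stored as positive magnitudes; the sign is applied in the rate equation.
#'
#' @param conn named list of connectivity matrices per projection
#' @param fan_tab fan-in table as from [fan_in_table()]
#' @param seed integer seed for the weight stream
#' @return named list of synapse groups: list(proj, sign, conn, raw, d, w)
#'   with `w = raw * d`
#' @export
init_weights <- function(conn, fan_tab, seed = 1L) {
  d_tab <- normalizers(fan_tab)
  groups <- list()
  with_stream(seed, {
    for (k in seq_len(nrow(fan_tab))) {
      p <- fan_tab$proj[k]
      cm <- conn[[p]]
      raw <- matrix(rnorm_trunc(length(cm), 0.9, 0.1, 0.8, 1),
                    nrow = nrow(cm), ncol = ncol(cm))
      d <- d_tab[[paste(fan_tab$dst[k], fan_tab$sign[k], sep = ".")]]
      groups[[p]] <- list(proj = p, sign = fan_tab$sign[k], conn = cm,
                          raw = raw, d = d, w = raw * d)
    }
  })
  groups
}

#' Build one hemisphere of the cerebellar network
#'
#' Runs the full 3D construction: random placement of each population in the
#' tissue cube, nearest-neighbour wiring under the convergence (fan-in)
#' contract, and truncated-normal weight initialization with cell-wise
#' normalization. Three independently seedable streams govern placement,
#' wiring and weights so experiment factorials can vary them separately.
#'
#' @param counts named population counts, default [default_counts()]
#' @param edge_um tissue cube edge length (micrometers)
#' @param seeds list with integer elements `placement`, `connectivity`,
#'   `weights`
#' @param fan_tab fan-in table; default derived from `counts`
#' @param sigma,mu activation slope and threshold (defaults 8 and 1/2)
#' @return an object of class `hemisphere_net`
#' @export
build_hemisphere <- function(counts = default_counts(), edge_um = 100,
                             seeds = list(placement = 1L, connectivity = 1L,
                                          weights = 1L),
                             fan_tab = fan_in_table(counts),
                             sigma = 8, mu = 0.5) {
  stopifnot(all(cell_kinds() %in% names(counts)))
  layouts <- list()
  for (i in seq_along(cell_kinds())) {
    k <- cell_kinds()[i]
    layouts[[k]] <- place_neurons(k, counts[[k]], edge_um,
                                  seed = derive_seed(seeds$placement, i))
  }
  # Positions fully determine nearest-neighbour wiring; the connectivity
  # stream is reserved for stochastic wiring variants and, importantly, lets
  # the experiments module re-place cells under a new "Net" identity (a fresh
  # connectivity table) while reusing a weight stream.
  conn <- list()
  for (k in seq_len(nrow(fan_tab))) {
    conn[[fan_tab$proj[k]]] <- wire_nearest_neighbor(
      layouts[[fan_tab$dst[k]]], layouts[[fan_tab$src[k]]],
      fan_tab$fan_in[k], proj = fan_tab$proj[k])
  }
  syn <- init_weights(conn, fan_tab, seed = seeds$weights)
  net <- structure(list(
    counts = vapply(cell_kinds(), function(k) as.integer(counts[[k]]),
                    integer(1)),
    edge_um = edge_um,
    seeds = seeds,
    fan_tab = fan_tab,
    layouts = layouts,
    syn = syn,
    sigma = sigma, mu = mu,
    active = rep(TRUE, counts[["GC"]]),
    comp_scale = 1
  ), class = "hemisphere_net")
  net
}

#' @export
print.hemisphere_net <- function(x, ...) {
  cat("<hemisphere_net>", paste(names(x$counts), x$counts, sep = "=",
                                collapse = " "), "\n")
  cat("  cube edge:", x$edge_um, "um; active GCs:", sum(x$active),
      "/", x$counts[["GC"]], "(compensation x", format(x$comp_scale), ")\n")
  invisible(x)
}

#' Knock down granule cells
#'
#' Silences all but `n_active` uniformly chosen GCs. A knocked-down GC emits
#' zero output everywhere. The surviving GC efferents (PF->GO, PF->BC,
#' PF->PC) are rescaled by total/active (equivalently, the excitatory
#' normalizer d is recomputed over active inputs) so the expected summed
#' excitatory drive onto downstream cells is preserved. All non-GC
#' populations and non-GC-originating synapses are untouched.
#'
#' @param net a `hemisphere_net`
#' @param n_active number of GCs to keep active (1..n_GC)
#' @param seed integer seed for the knockdown stream
#' @return the modified `hemisphere_net`
#' @export
knockdown_gcs <- function(net, n_active, seed = 1L) {
  n_gc <- net$counts[["GC"]]
  if (n_active < 1 || n_active > n_gc) {
    stop("refusing knockdown: n_active must be in [1, ", n_gc,
         "] (network output undefined with 0 active GCs)")
  }
  n_active <- as.integer(n_active)
  if (n_active == n_gc) {
    net$active <- rep(TRUE, n_gc)
    net$comp_scale <- 1
    return(net)
  }
  keep <- with_stream(seed, sort(sample.int(n_gc, n_active)))
  net$active <- rep(FALSE, n_gc)
  net$active[keep] <- TRUE
  net$comp_scale <- n_gc / n_active
  net
}

#' Validate the structural contract of a built hemisphere
#'
#' Checks, per projection, that every target cell has exactly the required
#' fan-in of distinct, in-range source indices, and that the same-sign
#' normalizers of every cell sum to one.
#'
#' @param net a `hemisphere_net`
#' @return a data.frame report (projection, expected fan-in, observed range,
#'   pass flag, message); attribute `ok` is TRUE when all rows pass
#' @export
validate_structure <- function(net) {
  tab <- net$fan_tab
  rows <- list()
  for (k in seq_len(nrow(tab))) {
    p <- tab$proj[k]
    cm <- net$syn[[p]]$conn
    n_src <- net$counts[[tab$src[k]]]
    ok <- TRUE; msg <- "ok"
    if (ncol(cm) != tab$fan_in[k]) {
      ok <- FALSE
      msg <- sprintf("fan-in %d != required %d", ncol(cm), tab$fan_in[k])
    } else if (nrow(cm) > 0L &&
               (min(cm) < 1L || max(cm) > n_src)) {
      ok <- FALSE; msg <- "source index out of range"
    } else if (nrow(cm) > 0L) {
      dup <- which(apply(cm, 1L, anyDuplicated) > 0L)
      if (length(dup) > 0L) {
        ok <- FALSE
        msg <- sprintf("duplicate afferents on target cell(s) %s",
                       paste(utils::head(dup, 3L), collapse = ","))
      }
    }
    rows[[k]] <- data.frame(
      projection = p, expected_fan_in = tab$fan_in[k],
      observed_fan_in = ncol(cm), n_targets = nrow(cm),
      pass = ok, message = msg, stringsAsFactors = FALSE)
  }
  # d-normalization: sum of d over same-sign inputs equals 1 for every cell
  d_tab <- normalizers(tab)
  for (key in names(d_tab)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    n_in <- sum(tab$fan_in[tab$dst == parts[1] & tab$sign == parts[2]])
    s <- d_tab[[key]] * n_in
    ok <- isTRUE(all.equal(s, 1))
    rows[[length(rows) + 1L]] <- data.frame(
      projection = paste0("d:", key), expected_fan_in = NA_integer_,
      observed_fan_in = NA_integer_, n_targets = n_in, pass = ok,
      message = if (ok) "ok" else sprintf("sum(d) = %.17g != 1", s),
      stringsAsFactors = FALSE)
  }
  rep <- do.call(rbind, rows)
  attr(rep, "ok") <- all(rep$pass)
  rep
}

#' Build the bi-hemispheric model
#'
#' Constructs a left and a right hemisphere. With `mirror = TRUE` both
#' hemispheres share the same streams and are identical (useful to verify
#' symmetric cancellation of the combined output); by default each
#' hemisphere gets its own derived child streams, as two singular instances
#' of the same microcircuit.
#'
#' @inheritParams build_hemisphere
#' @param mirror build both hemispheres from identical streams
#' @return an object of class `bicnn_model`: list(left, right)
#' @export
build_bicnn <- function(counts = default_counts(), edge_um = 100,
                        seeds = list(placement = 1L, connectivity = 1L,
                                     weights = 1L),
                        mirror = FALSE, sigma = 8, mu = 0.5) {
  hemi_seeds <- function(tag) {
    if (mirror) return(seeds)
    list(placement = derive_seed(seeds$placement, 100L + tag),
         connectivity = derive_seed(seeds$connectivity, 200L + tag),
         weights = derive_seed(seeds$weights, 300L + tag))
  }
  structure(list(
    left = build_hemisphere(counts, edge_um, hemi_seeds(1L),
                            sigma = sigma, mu = mu),
    right = build_hemisphere(counts, edge_um, hemi_seeds(2L),
                             sigma = sigma, mu = mu),
    seeds = seeds, mirror = mirror
  ), class = "bicnn_model")
}

#' @export
print.bicnn_model <- function(x, ...) {
  cat("<bicnn_model> two hemispheres,",
      paste(names(x$left$counts), x$left$counts, sep = "=", collapse = " "),
      if (x$mirror) "(mirrored)" else "", "\n")
  invisible(x)
}

#' Knock down granule cells in both hemispheres
#'
#' @param model a `bicnn_model`
#' @param n_active active GCs per hemisphere
#' @param seed integer seed; each hemisphere draws its mask from a derived
#'   child stream (the same stream when the model is mirrored)
#' @return the modified model
#' @export
knockdown_bicnn <- function(model, n_active, seed = 1L) {
  sl <- if (model$mirror) seed else derive_seed(seed, 401L)
  sr <- if (model$mirror) seed else derive_seed(seed, 402L)
  model$left <- knockdown_gcs(model$left, n_active, seed = sl)
  model$right <- knockdown_gcs(model$right, n_active, seed = sr)
  model
}
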