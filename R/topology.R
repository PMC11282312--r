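#' Cluster membership of all units
#'
#' Units are numbered 1..N with the excitatory population first. Cluster
#' membership is assigned in contiguous index blocks (unit id -> cluster =
#' floor(id / cluster size)), which makes assignments reproducible without an
#' extra random draw.
#'
#' @param spec a [network_spec()].
#' @param cluster_I logical; also divide the inhibitory population into
#'   \code{Q} clusters (E/I-clustered and E+I-variant topologies).
#' @return Data frame with columns \code{unit}, \code{population} ("E"/"I"),
#'   \code{cluster} (0-based index, \code{NA} for unclustered units).
#' @export
cluster_assignment <- function(spec, cluster_I = FALSE) {
  ns <- population_sizes(spec)
  Q <- spec$Q
  if (Q >= 2 && ns[["E"]] %% Q != 0)
    stop("N_E = ", ns[["E"]], " is not divisible by Q = ", Q)
  if (cluster_I && Q >= 2 && ns[["I"]] %% Q != 0)
    stop("N_I = ", ns[["I"]], " is not divisible by Q = ", Q)
  cl_E <- if (Q >= 2) (seq_len(ns[["E"]]) - 1L) %/% (ns[["E"]] %/% Q)
          else rep(NA_integer_, ns[["E"]])
  cl_I <- if (cluster_I && Q >= 2)
            (seq_len(ns[["I"]]) - 1L) %/% (ns[["I"]] %/% Q)
          else rep(NA_integer_, ns[["I"]])
  data.frame(unit = seq_len(spec$N),
             population = rep(c("E", "I"), ns),
             cluster = c(as.integer(cl_E), as.integer(cl_I)))
}

# Shared Bernoulli-connectivity builder. `kind` selects which weight classes
# receive within/across cluster scaling:
#   random: none; E: E->E only; EI: E->E by J_E+/-, EI/IE/II by J_I+/-;
#   E+I: E->E by J_E+/-, E->I (i.e. excitatory input to I units) by J_I+/-.
build_connectivity <- function(spec, kind, scaling = NULL, seed = NULL) {
  validate_network_spec(spec)
  kind <- match.arg(kind, c("random", "E", "EI", "E+I"))
  if (kind != "random" && is.null(scaling))
    scaling <- cluster_scaling(spec$Q, spec$J_Eplus, spec$R_J)
  units <- cluster_assignment(spec, cluster_I = kind %in% c("EI", "E+I"))
  w <- compute_weights(spec)
  ns <- population_sizes(spec)
  N <- spec$N
  is_E <- units$population == "E"
  cl <- units$cluster

  # per-target-row connection probability and base weight, by source pop
  p <- spec$p
  prob_src <- list(
    E = c(rep(p[["p_EE"]], ns[["E"]]), rep(p[["p_IE"]], ns[["I"]])),
    I = c(rep(p[["p_EI"]], ns[["E"]]), rep(p[["p_II"]], ns[["I"]])))
  base_src <- list(
    E = c(rep(w[["J_EE"]], ns[["E"]]), rep(w[["J_IE"]], ns[["I"]])),
    I = c(rep(w[["J_EI"]], ns[["E"]]), rep(w[["J_II"]], ns[["I"]])))

  with_seed(seed, {
    idx_list <- vector("list", N)
    x_list <- vector("list", N)
    for (j in seq_len(N)) {
      src <- if (is_E[j]) "E" else "I"
      idx <- which(runif(N) < prob_src[[src]])
      idx <- idx[idx != j]                       # no autapses
      wts <- base_src[[src]][idx]
      if (kind != "random") {
        same <- !is.na(cl[idx]) & !is.na(cl[j]) & cl[idx] == cl[j]
        tgt_E <- idx <= ns[["E"]]
        if (is_E[j]) {
          ee <- tgt_E
          wts[ee] <- wts[ee] *
            ifelse(same[ee], scaling$J_Eplus, scaling$J_Eminus)
          if (kind %in% c("EI", "E+I")) {         # E -> I
            ei <- !tgt_E
            wts[ei] <- wts[ei] *
              ifelse(same[ei], scaling$J_Iplus, scaling$J_Iminus)
          }
        } else if (kind == "EI") {                # I -> E and I -> I
          wts <- wts * ifelse(same, scaling$J_Iplus, scaling$J_Iminus)
        }
      }
      idx_list[[j]] <- idx
      x_list[[j]] <- wts
    }
  })
  counts <- lengths(idx_list)
  W <- new("dgCMatrix",
           i = as.integer(unlist(idx_list) - 1L),
           p = as.integer(c(0L, cumsum(counts))),
           x = as.numeric(unlist(x_list)),
           Dim = c(as.integer(N), as.integer(N)))
  structure(list(W = W, units = units, kind = kind, scaling = scaling,
                 seed = seed, spec = spec),
            class = "connectivity")
}

#' Build network connectivity
#'
#' Draws the signed, weighted synaptic connectivity of a balanced network.
#' Every ordered pair (target i, source j), i != j, is connected
#' independently with the probability of its population pair; connected
#' entries carry the calibrated base efficacy ([compute_weights()]) times the
#' cluster scaling factor of the topology:
#' \describe{
#'   \item{\code{build_random_balanced}}{no clustering.}
#'   \item{\code{build_e_clustered}}{excitatory-to-excitatory weights scaled
#'     by \code{J_Eplus} within and \code{J_Eminus} across clusters; all
#'     inhibitory-related weights unscaled.}
#'   \item{\code{build_ei_clustered}}{additionally scales the EI, IE and II
#'     weights by \code{J_Iplus} within cluster pairs and \code{J_Iminus}
#'     across, so that each excitatory cluster is balanced by its own
#'     inhibitory cluster.}
#'   \item{\code{build_e_plus_i_variant}}{only the unidirectional excitatory
#'     input to the inhibitory clusters is scaled (besides the E-to-E
#'     clustering); inhibitory outputs remain unspecific.}
#' }
#'
#' @param spec a [network_spec()].
#' @param scaling a [cluster_scaling()]; defaults to the one implied by
#'   \code{spec} (\code{Q}, \code{J_Eplus}, \code{R_J}).
#' @param seed integer seed for the Bernoulli draws (restores the caller's
#'   RNG state afterwards).
#' @return An object of class \code{connectivity}: list with the sparse
#'   weight matrix \code{W} (entry \code{[i, j]} = efficacy from presynaptic
#'   \code{j} to postsynaptic \code{i}, pA), the unit metadata frame
#'   \code{units}, the topology \code{kind}, \code{scaling} and \code{seed}.
#' @examples
#' spec <- network_spec(N = 200, Q = 4, J_Eplus = 2)
#' conn <- build_ei_clustered(spec, seed = 1)
#' @export
build_random_balanced <- function(spec, seed = NULL)
  build_connectivity(spec, "random", seed = seed)

#' @rdname build_random_balanced
#' @export
build_e_clustered <- function(spec, scaling = NULL, seed = NULL)
  build_connectivity(spec, "E", scaling, seed)

#' @rdname build_random_balanced
#' @export
build_ei_clustered <- function(spec, scaling = NULL, seed = NULL)
  build_connectivity(spec, "EI", scaling, seed)

#' @rdname build_random_balanced
#' @export
build_e_plus_i_variant <- function(spec, scaling = NULL, seed = NULL)
  build_connectivity(spec, "E+I", scaling, seed)

#' @export
print.connectivity <- function(x, ...) {
  cat("<connectivity>", x$kind, "topology,", nrow(x$W), "units,",
      length(x$W@x), "synapses\n")
  invisible(x)
}

#' Export / import connectivity as coordinate-list CSV
#'
#' Writes the edge list (\code{pre_id}, \code{post_id}, \code{weight_pA}) and
#' the unit metadata (\code{unit}, \code{population}, \code{cluster}) as two
#' CSV files.
#'
#' @param conn a \code{connectivity} object.
#' @param edge_path,units_path output file paths.
#' @return \code{read_connectivity_csv} returns a \code{connectivity} object
#'   (without spec/scaling metadata).
#' @export
write_connectivity_csv <- function(conn, edge_path, units_path) {
  tw <- Matrix::summary(conn$W)
  write.csv(data.frame(pre_id = tw$j, post_id = tw$i, weight_pA = tw$x),
            edge_path, row.names = FALSE)
  write.csv(conn$units, units_path, row.names = FALSE)
  invisible(edge_path)
}

#' @rdname write_connectivity_csv
#' @export
read_connectivity_csv <- function(edge_path, units_path) {
  ed <- read.csv(edge_path)
  units <- read.csv(units_path)
  N <- nrow(units)
  W <- Matrix::sparseMatrix(i = ed$post_id, j = ed$pre_id, x = ed$weight_pA,
                            dims = c(N, N))
  structure(list(W = methods::as(W, "CsparseMatrix"), units = units,
                 kind = "imported", scaling = NULL, seed = NULL, spec = NULL),
            class = "connectivity")
}
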