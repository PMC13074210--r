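#' @useDynLib fretKinetics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats rexp runif rnorm rpois rbinom optim sd setNames
#'   dbinom quantile approx integrate median var IQR ks.test ecdf
#' @importFrom graphics hist
#' @importFrom utils head tail read.table write.table modifyList
NULL

.ZERO_EV_REL_TOL <- 1e-10

#' KineticNetwork: an N-state first-order kinetic network
#'
#' Holds the transition rate matrix \eqn{K} of a continuous-time Markov
#' kinetic network. The convention is \eqn{K[i,j] = k_{ij}}, the rate of
#' transition *from state j to state i* (in 1/ms), so that the species
#' fractions evolve as \eqn{dx/dt = K x}. Diagonal entries are the negative
#' column sums of the off-diagonal rates, hence every column of \eqn{K}
#' sums to zero and \eqn{exp(Kt)} is a stochastic propagator.
#'
#' @slot K numeric matrix, rates in 1/ms; columns sum to zero.
#' @slot stateLabels character vector of short state names.
#' @export
setClass("KineticNetwork",
  representation(K = "matrix", stateLabels = "character"),
  validity = function(object) {
    K <- object@K
    n <- nrow(K)
    msg <- character()
    if (ncol(K) != n) msg <- c(msg, "K must be square")
    if (length(object@stateLabels) != n)
      msg <- c(msg, "need one state label per state")
    off <- K; diag(off) <- 0
    if (any(off < 0)) msg <- c(msg, "off-diagonal rates must be >= 0")
    cs <- colSums(K)
    tol <- 1e-12 * max(1, max(abs(K)))
    if (any(abs(cs) > tol)) msg <- c(msg, "columns of K must sum to zero")
    if (length(msg)) msg else TRUE
  })

#' Build the transition rate matrix of a kinetic network
#'
#' @param n number of states.
#' @param rates a data.frame with columns `from`, `to`, `rate` (1/ms);
#'   `from`/`to` may be state indices or labels. Unspecified pairs default
#'   to zero. Alternatively `NULL` for a fully static (all-zero) network.
#' @param labels optional state labels (default `"S1"..."Sn"`).
#' @return a [KineticNetwork-class] object.
#' @examples
#' net <- kineticNetwork(2, data.frame(from = 1, to = 2, rate = 5))
#' rateMatrix(net)
#' @export
kineticNetwork <- function(n, rates = NULL, labels = NULL) {
  if (is.null(labels)) labels <- paste0("S", seq_len(n))
  if (length(labels) != n) stop("need ", n, " labels")
  K <- matrix(0, n, n, dimnames = list(labels, labels))
  if (!is.null(rates) && nrow(rates) > 0) {
    idx <- function(s) {
      if (is.numeric(s)) return(as.integer(s))
      m <- match(as.character(s), labels)
      if (anyNA(m)) stop("unknown state label: ",
                         paste(s[is.na(m)], collapse = ", "))
      m
    }
    from <- idx(rates$from); to <- idx(rates$to)
    r <- as.numeric(rates$rate)
    if (any(r < 0)) stop("rates must be >= 0")
    if (any(from == to)) stop("self-transitions cannot be specified")
    if (any(from < 1 | from > n | to < 1 | to > n))
      stop("state index out of range")
    for (i in seq_along(r)) K[to[i], from[i]] <- K[to[i], from[i]] + r[i]
    diag(K) <- 0
    diag(K) <- -colSums(K)
  }
  new("KineticNetwork", K = K, stateLabels = labels)
}

#' @describeIn kineticNetwork number of states
#' @param net a KineticNetwork
#' @export
nStates <- function(net) nrow(net@K)

#' @describeIn kineticNetwork the rate matrix (1/ms)
#' @export
rateMatrix <- function(net) net@K

#' @describeIn kineticNetwork state labels
#' @export
stateLabels <- function(net) net@stateLabels

setMethod("show", "KineticNetwork", function(object) {
  cat(sprintf("KineticNetwork with %d states: %s\n", nStates(object),
              paste(object@stateLabels, collapse = ", ")))
  cat("Rate matrix K (1/ms), K[i,j] = rate j -> i:\n")
  print(round(object@K, 6))
})

## strong connectivity of the directed rate graph (edge j -> i iff K[i,j] > 0)
.connectedComponents <- function(K) {
  n <- nrow(K)
  reach <- function(adj, s) {
    seen <- logical(n); seen[s] <- TRUE; stack <- s
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      nb <- which(adj[, v] & !seen)
      seen[nb] <- TRUE; stack <- c(stack, nb)
    }
    seen
  }
  adj <- K > 0; diag(adj) <- FALSE
  fwd <- reach(adj, 1L)
  bwd <- reach(t(adj), 1L)
  fwd & bwd
}

.isIrreducible <- function(net) all(.connectedComponents(net@K))

#' Equilibrium species fractions of a kinetic network
#'
#' Solves \eqn{K x = 0, \sum_i x_i = 1}. For a two-state network this is
#' \eqn{x^{(1)} = k_{12}/(k_{12}+k_{21})}.
#'
#' @param net a [KineticNetwork-class]; must be irreducible.
#' @return numeric vector of equilibrium fractions (sums to 1).
#' @export
equilibriumFractions <- function(net) {
  K <- net@K
  n <- nrow(K)
  comp <- .connectedComponents(K)
  if (!all(comp))
    stop("network is reducible; states disconnected from '",
         net@stateLabels[1], "': ",
         paste(net@stateLabels[!comp], collapse = ", "))
  A <- rbind(K, rep(1, n))
  x <- qr.solve(A, c(rep(0, n), 1))
  x[x < 0 & x > -1e-12] <- 0
  if (any(x < 0)) stop("negative equilibrium fraction; invalid rate matrix")
  setNames(x / sum(x), net@stateLabels)
}

#' Equilibrium constant of a two-state network
#'
#' \eqn{K_{eq} = x^{(2)}_d / x^{(1)}_d = k_{21}/k_{12}}.
#'
#' @param net a two-state [KineticNetwork-class].
#' @return scalar equilibrium constant.
#' @export
equilibriumConstant <- function(net) {
  if (nStates(net) != 2) stop("equilibriumConstant requires exactly 2 states")
  x <- equilibriumFractions(net)
  unname(x[2] / x[1])
}

#' Fraction-weighted mean FRET efficiency
#'
#' \eqn{\langle E \rangle = \sum_i x^{(i)} E^{(i)}}.
#'
#' @param x species fractions (must sum to 1).
#' @param E species FRET efficiencies.
#' @return scalar mean efficiency.
#' @export
meanEfficiency <- function(x, E) {
  if (length(x) != length(E)) stop("length mismatch between x and E")
  if (abs(sum(x) - 1) > 1e-8) stop("fractions must sum to 1")
  sum(x * E)
}

#' KineticEigen: spectral decomposition of a rate matrix
#'
#' Eigen-decomposition \eqn{K = \sum_l \Gamma^{(l)} \lambda^{(l)}} with
#' spectral projectors \eqn{\Gamma^{(l)}}, so that
#' \eqn{exp(K t) = \sum_l \Gamma^{(l)} e^{\lambda^{(l)} t}}. Nonzero
#' eigenvalues map to FCS relaxation times \eqn{t_R^{(l)} = -1/\lambda^{(l)}}.
#'
#' @slot eigenvalues numeric, 1/ms, sorted with the zero eigenvalue first,
#'   then by decreasing relaxation time.
#' @slot projectors list of n x n projector matrices.
#' @slot relaxationTimes numeric, ms, one per nonzero eigenvalue.
#' @export
setClass("KineticEigen",
  representation(eigenvalues = "numeric", projectors = "list",
                 relaxationTimes = "numeric"))

setMethod("show", "KineticEigen", function(object) {
  cat(sprintf("KineticEigen: %d eigenvalues (1/ms): %s\n",
              length(object@eigenvalues),
              paste(signif(object@eigenvalues, 6), collapse = ", ")))
  if (length(object@relaxationTimes))
    cat("Relaxation times (ms):",
        paste(signif(object@relaxationTimes, 6), collapse = ", "), "\n")
})

.detailedBalance <- function(K, x, tol = 1e-9) {
  n <- nrow(K)
  f <- K * rep(x, each = n)      # f[i,j] = k_ij x_j : flux j -> i
  d <- f - t(f); diag(d) <- 0
  max(abs(d)) <= tol * max(abs(f), 1e-300)
}

#' Eigen-decompose a kinetic network
#'
#' For networks obeying detailed balance the non-symmetric \eqn{K} is made
#' symmetric by the similarity transform with \eqn{diag(\sqrt{x_{eq}})},
#' which guarantees a real spectrum and orthogonal projectors; a general
#' eigen solver is the fallback.
#'
#' @param net a [KineticNetwork-class].
#' @return a [KineticEigen-class].
#' @export
eigenDecompose <- function(net) {
  K <- net@K
  n <- nrow(K)
  tolz <- .ZERO_EV_REL_TOL * max(abs(K), 1)
  use_sym <- .isIrreducible(net)
  if (use_sym) {
    x <- equilibriumFractions(net)
    use_sym <- all(x > 0) && .detailedBalance(K, x)
  }
  if (use_sym) {
    s <- sqrt(x)
    S <- K * outer(1 / s, s)           # D^{-1/2} K D^{1/2}, symmetric
    S <- (S + t(S)) / 2
    es <- eigen(S, symmetric = TRUE)
    lam <- es$values
    V <- es$vectors * s                # right eigenvectors
    W <- t(es$vectors / s)             # left eigenvectors (rows), W V = I
  } else {
    es <- eigen(K)
    lam <- es$values
    V <- es$vectors
    W <- tryCatch(solve(V), error = function(e)
      stop("rate matrix appears defective; a symmetrized solver requires ",
           "detailed balance"))
    if (is.complex(lam)) {
      if (max(abs(Im(lam))) > 1e-8 * max(abs(lam)))
        warning("complex eigenvalue pair in non-detailed-balance network")
      lam <- Re(lam); V <- Re(V); W <- Re(W)
    }
  }
  zero <- abs(lam) < tolz
  lam[zero] <- 0
  # zero eigenvalue(s) first, then decreasing relaxation time magnitude
  ord <- c(which(zero), setdiff(order(abs(lam)), which(zero)))
  lam <- lam[ord]; V <- V[, ord, drop = FALSE]; W <- W[ord, , drop = FALSE]
  proj <- lapply(seq_len(n), function(l)
    V[, l, drop = FALSE] %*% W[l, , drop = FALSE])
  tR <- -1 / lam[lam != 0]
  new("KineticEigen", eigenvalues = lam, projectors = proj,
      relaxationTimes = tR)
}

#' @describeIn eigenDecompose relaxation times (ms) of a network or
#'   decomposition
#' @param x a KineticNetwork or KineticEigen
#' @export
relaxationTimes <- function(x) {
  if (is(x, "KineticNetwork")) x <- eigenDecompose(x)
  x@relaxationTimes
}

#' Propagator exp(K t) from the spectral decomposition
#'
#' @param es a [KineticEigen-class] (or [KineticNetwork-class]).
#' @param t time in ms.
#' @return the n x n matrix \eqn{\sum_l \Gamma^{(l)} e^{\lambda^{(l)} t}}.
#' @export
propagator <- function(es, t) {
  if (is(es, "KineticNetwork")) es <- eigenDecompose(es)
  Reduce(`+`, Map(function(G, l) G * exp(l * t),
                  es@projectors, as.list(es@eigenvalues)))
}

#' Serialize / read a kinetic network as a structured config
#'
#' The on-disk format is YAML with `states:` (labels) and `rates:` (list of
#' "from,to,rate_per_ms" triples); round-trips exactly.
#'
#' @param net a [KineticNetwork-class].
#' @param path file path.
#' @export
writeKineticNetwork <- function(net, path) {
  K <- net@K
  off <- which(K > 0 & row(K) != col(K), arr.ind = TRUE)
  triples <- apply(off, 1, function(ij)
    sprintf("%s,%s,%.17g", net@stateLabels[ij[2]], net@stateLabels[ij[1]],
            K[ij[1], ij[2]]))
  yaml::write_yaml(list(states = as.list(net@stateLabels),
                        rates = as.list(unname(triples))), path)
  invisible(path)
}

#' @rdname writeKineticNetwork
#' @export
readKineticNetwork <- function(path) {
  cfg <- yaml::read_yaml(path)
  labels <- unlist(cfg$states)
  if (length(cfg$rates)) {
    parts <- do.call(rbind, strsplit(unlist(cfg$rates), ","))
    rates <- data.frame(from = parts[, 1], to = parts[, 2],
                        rate = as.numeric(parts[, 3]))
  } else rates <- NULL
  kineticNetwork(length(labels), rates, labels)
}
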