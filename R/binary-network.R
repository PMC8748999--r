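#' Discrete Laplacian of a binary field at one site
#'
#' `sum(neighbors) - n_neighbors * S_site` with 4 neighbors in 2-D (range
#' -4..4) and 2 in 1-D, periodic boundary.
#'
#' @param S binary matrix (2-D) or vector (1-D).
#' @param site `c(i, j)` (2-D) or index (1-D), 1-based.
#' @return integer Laplacian value.
#' @export
discreteLaplacian <- function(S, site) {
  if (is.matrix(S)) {
    nx <- nrow(S); ny <- ncol(S)
    i <- site[1]; j <- site[2]
    if (i < 1 || i > nx || j < 1 || j > ny) stop("site outside lattice")
    wrap <- function(k, n) ((k - 1) %% n) + 1
    S[wrap(i + 1, nx), j] + S[wrap(i - 1, nx), j] +
      S[i, wrap(j + 1, ny)] + S[i, wrap(j - 1, ny)] - 4L * S[i, j]
  } else {
    n <- length(S)
    i <- site[1]
    if (i < 1 || i > n) stop("site outside lattice")
    wrap <- function(k) ((k - 1) %% n) + 1
    S[wrap(i + 1)] + S[wrap(i - 1)] - 2L * S[i]
  }
}

## Neighbor list (0-based, padded with -1) of a periodic lattice, for the
## exact continuous-time simulator and the master-equation generator.
latticeNeighbors <- function(side, dimension) {
  if (dimension == 1L) {
    n <- side
    nbr <- vapply(seq_len(n) - 1L, function(i)
      as.integer(c((i + 1) %% n, (i - 1 + n) %% n)), integer(2))
    if (n == 2) nbr <- matrix(nbr[1, ], nrow = 1)   # avoid duplicate edges
  } else {
    n <- side^2
    idx <- function(x, y) as.integer((x %% side) + side * (y %% side))
    nbr <- vapply(seq_len(n) - 1L, function(i) {
      x <- i %% side; y <- i %/% side
      v <- c(idx(x + 1, y), idx(x - 1 + side, y),
             idx(x, y + 1), idx(x, y - 1 + side))
      if (side == 2) v <- unique(v)
      c(v, rep(-1L, 4L - length(v)))
    }, integer(4))
  }
  nbr <- as.matrix(nbr)
  storage.mode(nbr) <- "integer"
  nbr
}

#' Simulate the binary-unit (Glauber-type) network
#'
#' Synchronous updating flips every unit independently each `updateBin`
#' with probability `clip(w * dt, 0, 1)` where `w` is its current transition
#' rate (Off-to-On `alpha1 + beta1 * Lap`, On-to-Off `alpha2 - beta2 * Lap`;
#' negative rates clipped at zero). The asynchronous mode is an exact
#' continuous-time (Gillespie) realization of the master equation, sampled
#' on the same `updateBin` grid; stationary statistics should agree between
#' the schemes up to time-discretization error.
#'
#' @param params a [BinaryNetParams-class].
#' @param duration simulated time (s).
#' @param seed integer seed.
#' @param update `"synchronous"` (10 ms binned updates) or
#'   `"asynchronous"` (exact continuous time).
#' @param S0 initial binary field (matrix side x side, or vector in 1-D);
#'   default independent draws from the uncoupled stationary probability.
#' @param recordEvery record every this many update bins.
#' @return a [StateField-class] with one trial; `meta$clipped` counts
#'   rate-clipping events in the synchronous scheme.
#' @export
simulateBinary <- function(params, duration, seed = 1L,
                           update = c("synchronous", "asynchronous"),
                           S0 = NULL, recordEvery = 1L) {
  stopifnot(is(params, "BinaryNetParams"))
  validObject(params)
  update <- match.arg(update)
  dt <- params@updateBin
  nsteps <- as.integer(round(duration / dt))
  if (nsteps < 1) stop("duration shorter than one update bin")
  if (max(params@alpha1, params@alpha2) * dt > 0.5)
    warning("baseline rate times updateBin exceeds 0.5; ",
            "time-discretization error will be large")
  side <- params@side
  set.seed(seed)
  p1 <- params@alpha1 / max(params@alpha1 + params@alpha2, 1e-300)
  if (params@dimension == 2L) {
    if (is.null(S0)) S0 <- matrix(as.integer(runif(side^2) < p1), side, side)
    S0 <- matrix(as.integer(S0), side, side)
  } else {
    if (is.null(S0)) S0 <- as.integer(runif(side) < p1)
    S0 <- matrix(as.integer(S0), side, 1)    # 1-D as a degenerate matrix
  }
  if (update == "synchronous") {
    if (params@dimension == 1L)
      stop("synchronous updating is implemented for 2-D lattices; ",
           "use update = 'asynchronous' for 1-D")
    out <- cpp_simulate_binary(S0, nsteps, dt, params@alpha1, params@alpha2,
                               params@beta1, params@beta2,
                               as.integer(recordEvery))
    arr <- array(out$S, dim = c(side, side, nsteps %/% recordEvery))
    clipped <- out$clipped
  } else {
    nbr <- latticeNeighbors(side, params@dimension)
    samp <- cpp_gillespie_binary(as.integer(S0), nbr, params@alpha1,
                                 params@alpha2, params@beta1, params@beta2,
                                 duration, dt * recordEvery)
    nrec <- ncol(samp)
    if (params@dimension == 2L) arr <- array(samp, dim = c(side, side, nrec))
    else arr <- array(samp, dim = c(side, 1, nrec))
    clipped <- NA_integer_
  }
  new("StateField", fields = list(arr), dt = dt * recordEvery,
      meta = list(params = params, seed = as.integer(seed), update = update,
                  clipped = clipped))
}

#' Exact stationary distribution of a small binary-unit network
#'
#' Enumerates all `2^N` configurations, builds the master-equation
#' generator from the Glauber-type single-flip rates and returns its
#' stationary distribution (null space of the transposed generator). If the
#' rate graph is reducible (e.g. `alpha1 = 0` makes all-Off absorbing), all
#' closed communicating classes are reported instead of a unique
#' distribution.
#'
#' @param params a [BinaryNetParams-class]; `side`/`dimension` give the
#'   lattice unless `topology` overrides it.
#' @param nUnits number of units (<= 12).
#' @param topology optional neighbor matrix (0-based columns per unit,
#'   padded with -1) for arbitrary graphs.
#' @return list with `states` (N-column 0/1 matrix), `probability`
#'   (stationary probabilities; NA if reducible) and `classes` (list of
#'   recurrent classes when reducible).
#' @export
solveMasterEquation <- function(params, nUnits = params@side^params@dimension,
                                topology = NULL) {
  stopifnot(is(params, "BinaryNetParams"))
  if (nUnits > 12) stop("nUnits must be <= 12 (exact enumeration)")
  if (is.null(topology)) {
    side <- if (params@dimension == 2L) as.integer(sqrt(nUnits)) else as.integer(nUnits)
    if (params@dimension == 2L && side^2 != nUnits)
      stop("nUnits must be a square for a 2-D lattice")
    topology <- latticeNeighbors(side, params@dimension)
  }
  N <- nUnits
  nS <- 2L^N
  states <- vapply(seq_len(nS) - 1L, function(k)
    as.integer(bitwAnd(bitwShiftR(k, seq_len(N) - 1L), 1L)), integer(N))
  states <- if (N == 1L) matrix(states, ncol = 1L) else t(states)
  flipRate <- function(s, u) {
    nb <- topology[, u]; nb <- nb[nb >= 0] + 1L
    lap <- sum(s[nb]) - length(nb) * s[u]
    w <- if (s[u] == 1L) params@alpha2 - params@beta2 * lap
         else params@alpha1 + params@beta1 * lap
    max(w, 0)
  }
  G <- matrix(0, nS, nS)
  for (k in seq_len(nS)) {
    s <- states[k, ]
    for (u in seq_len(N)) {
      w <- flipRate(s, u)
      if (w > 0) {
        k2 <- k + (if (s[u] == 1L) -1L else 1L) * 2L^(u - 1L)
        G[k, k2] <- G[k, k2] + w
      }
    }
  }
  diag(G) <- -rowSums(G)
  ## recurrent classes of the embedded jump graph
  adj <- (G > 0)
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  comp <- igraph::components(gr, mode = "strong")
  cond <- igraph::contract(gr, comp$membership)
  cond <- igraph::simplify(cond)
  sinks <- which(igraph::degree(cond, mode = "out") == 0)
  classes <- lapply(sinks, function(cl) which(comp$membership == cl))
  if (length(classes) > 1) {
    return(list(states = states, probability = rep(NA_real_, nS),
                classes = classes))
  }
  A <- t(G)
  A[nS, ] <- 1
  b <- c(rep(0, nS - 1), 1)
  p <- solve(A, b)
  p[abs(p) < 1e-15] <- 0
  list(states = states, probability = p / sum(p), classes = classes)
}

#' Integrate the moment equations of the binary-unit network
#'
#' Integrates the first- and pair-moment dynamics of a
#' translation-invariant periodic lattice,
#' \deqn{d\langle S\rangle/dt = \alpha_1 - (\alpha_1+\alpha_2)\langle S\rangle,}
#' (the `beta1` term vanishes under translation invariance) and, for
#' displacements `delta != 0`,
#' \deqn{dC(\delta)/dt = 2\alpha_1 \langle S\rangle
#'   - 2(\alpha_1+\alpha_2) C(\delta) + 2\beta_1 \Delta_\delta C,}
#' where `Delta_delta` is the discrete Laplacian in displacement space and
#' `C(0) = <S>` (the binary identity) closes the hierarchy as written (the
#' pair equation carries `beta1` only).
#'
#' @param params a [BinaryNetParams-class] (`side` sets the displacement
#'   torus; `dimension` 1 or 2).
#' @param initial optional list with `m` (scalar first moment) and `C`
#'   (pair-moment grid over displacements: side x side in 2-D, length-side
#'   vector in 1-D); default uncorrelated at `m0`.
#' @param m0 initial occupancy when `initial` is NULL.
#' @param duration integration time (s).
#' @param nOut number of output time points.
#' @return list with `times`, `m` (first-moment trajectory), `C` (final
#'   pair-moment grid), `steadyState` (list `m`, `C` at the final time) and
#'   `distances`/`pairMoments` (radial profile of the final grid).
#' @export
integrateMoments <- function(params, initial = NULL, m0 = 0.5,
                             duration = 2, nOut = 50L) {
  stopifnot(is(params, "BinaryNetParams"))
  side <- params@side
  a1 <- params@alpha1; a2 <- params@alpha2; b1 <- params@beta1
  twoD <- params@dimension == 2L
  if (is.null(initial)) {
    m <- m0
    C <- if (twoD) matrix(m0^2, side, side) else rep(m0^2, side)
  } else {
    m <- initial$m
    C <- initial$C
  }
  C[1] <- m
  shift2 <- function(M, dx, dy) {
    idx <- ((seq_len(side) - 1 + dx) %% side) + 1
    idy <- ((seq_len(side) - 1 + dy) %% side) + 1
    M[idx, idy, drop = FALSE]
  }
  shift1 <- function(v, dx) v[((seq_len(side) - 1 + dx) %% side) + 1]
  rhs <- function(t, y, parms) {
    m <- y[1]
    if (twoD) {
      C <- matrix(y[-1], side, side)
      C[1, 1] <- m
      lap <- shift2(C, 1, 0) + shift2(C, -1, 0) + shift2(C, 0, 1) +
        shift2(C, 0, -1) - 4 * C
    } else {
      C <- y[-1]
      C[1] <- m
      lap <- shift1(C, 1) + shift1(C, -1) - 2 * C
    }
    dC <- 2 * a1 * m - 2 * (a1 + a2) * C + 2 * b1 * lap
    dm <- a1 - (a1 + a2) * m
    dC[1] <- dm
    list(c(dm, as.numeric(dC)))
  }
  times <- seq(0, duration, length.out = nOut)
  sol <- deSolve::ode(y = c(m, as.numeric(C)), times = times, func = rhs,
                      parms = NULL, method = "lsoda")
  mTraj <- sol[, 2]
  mInf <- mTraj[length(mTraj)]
  if (twoD) {
    Cfin <- matrix(sol[nrow(sol), -(1:2)], side, side)
    Cfin[1, 1] <- mInf
    dx <- pmin(seq_len(side) - 1, side - (seq_len(side) - 1))
    dist <- sqrt(outer(dx^2, dx^2, "+"))
    prof <- tapply(as.numeric(Cfin), round(as.numeric(dist), 6), mean)
    distances <- as.numeric(names(prof))
    pairMoments <- as.numeric(prof)
  } else {
    Cfin <- sol[nrow(sol), -(1:2)]
    Cfin[1] <- mInf
    dx <- pmin(seq_len(side) - 1, side - (seq_len(side) - 1))
    o <- order(dx)
    distances <- unique(dx[o])
    pairMoments <- as.numeric(tapply(Cfin, dx, mean))
  }
  list(times = times, m = mTraj, C = Cfin,
       steadyState = list(m = mInf, C = Cfin),
       distances = distances, pairMoments = pairMoments)
}

#' Spatial state correlation versus lattice distance
#'
#' Empirical pair correlation of a binary field as a function of lattice
#' distance, computed by FFT-based spatial autocorrelation of mean-removed
#' frames (averaged over time bins and trials) and binned by rounded
#' Euclidean offset length. With periodic fields the full torus is used;
#' within a rectangular region the non-periodic (zero-padded) estimate is
#' used.
#'
#' @param field a [StateField-class] (or a single x,y,bins array).
#' @param maxDist largest distance bin to report.
#' @param region optional list(x, y) of index ranges restricting the
#'   estimate to a patch (non-periodic estimate).
#' @param periodic treat the field as periodic (ignored when `region` is
#'   given).
#' @return data.frame with `d` (lattice units), `corr` (Pearson-normalized
#'   pair correlation) and `n` (offset pairs averaged per bin).
#' @export
stateCorrelationByDistance <- function(field, maxDist = 16, region = NULL,
                                       periodic = TRUE) {
  arrs <- if (is(field, "StateField")) stateArrays(field) else list(field)
  if (!is.null(region)) {
    arrs <- lapply(arrs, function(a) a[region$x, region$y, , drop = FALSE])
    periodic <- FALSE
  }
  nx <- dim(arrs[[1]])[1]; ny <- dim(arrs[[1]])[2]
  mu <- mean(vapply(arrs, mean, numeric(1)))
  px <- if (periodic) nx else 2 * nx
  py <- if (periodic) ny else 2 * ny
  num <- matrix(0, px, py)
  nFrames <- 0
  for (a in arrs) {
    nb <- dim(a)[3]
    for (b in seq_len(nb)) {
      X <- matrix(0, px, py)
      X[seq_len(nx), seq_len(ny)] <- a[, , b] - mu
      fX <- fft(X)
      num <- num + Re(fft(fX * Conj(fX), inverse = TRUE)) / (px * py)
      nFrames <- nFrames + 1
    }
  }
  cnt <- if (periodic) matrix(nx * ny, px, py) else {
    ones <- matrix(0, px, py)
    ones[seq_len(nx), seq_len(ny)] <- 1
    fo <- fft(ones)
    pmax(Re(fft(fo * Conj(fo), inverse = TRUE)) / (px * py), 1e-9)
  }
  cov <- num / (cnt * nFrames)
  offx <- c(0:(px %/% 2), -((px - px %/% 2 - 1):1))
  offy <- c(0:(py %/% 2), -((py - py %/% 2 - 1):1))
  dist <- sqrt(outer(offx^2, offy^2, "+"))
  keep <- dist <= maxDist + 0.5 & (if (periodic) TRUE else
    matrix(rep(abs(offx) < nx, py), px, py) &
      matrix(rep(abs(offy) < ny, each = px), px, py))
  db <- round(dist[keep])
  cv <- cov[keep]
  v <- cov[1, 1]
  prof <- tapply(cv, db, mean) / v
  npairs <- tapply(cnt[keep], db, sum)        # site pairs per frame
  data.frame(d = as.numeric(names(prof)), corr = as.numeric(prof),
             n = as.numeric(npairs))
}
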