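#' Discretize a vessel geometry into a fluid domain
#'
#' Voxelizes the lumen onto a uniform marker-and-cell (MAC) staggered grid:
#' pressure at cell centers, velocity components on cell faces. Cells are
#' classified fluid / wall from the tube signed distance (distance to the
#' centerline minus the local lumen radius); the first `inlet_len_mm` of
#' arclength is the velocity-prescribed inlet region, the last
#' `outlet_len_mm` the pressure-prescribed outlet region. Near-wall viscous
#' stencils carry the sub-cell distance to the true wall
#' (Shortley-Weller-type one-sided differences), so the no-slip boundary is
#' imposed at the actual lumen surface rather than at the staircase voxel
#' boundary.
#'
#' @param geom a `vessel_geometry`
#' @param cells_across_diameter grid cells across the mean lumen diameter
#'   (default 16; a 0.95 cm tube gives h ~ 0.59 mm)
#' @param inlet_len_mm,outlet_len_mm lengths of the inlet/outlet regions
#'   (default 3 cells each)
#' @param theta_min floor on the sub-cell wall distance fraction (stability
#'   of the explicit viscous update; default 0.25)
#' @return an object of class `fluid_domain`; its print method reports the
#'   cell size `h` and fluid cell count
#' @export
discretize <- function(geom, cells_across_diameter = 16L,
                       inlet_len_mm = NULL, outlet_len_mm = NULL,
                       theta_min = 0.25) {
  stopifnot(inherits(geom, "vessel_geometry"))
  if (!is_watertight(geom)) stop("geometry surface is not watertight")
  d_mean <- mean(geom$station_diameter) * 10       # mm
  h_mm <- d_mean / cells_across_diameter
  if (min(geom$station_diameter) * 10 < 4 * h_mm)
    stop("geometry thinner than 4 cells at its narrowest; use finer resolution")
  h <- h_mm * 1e-3                                 # m
  # fine centerline with per-point radius, in meters
  cl <- geom$centers * 1e-3
  s_st <- geom$station_s * 1e-3
  r_st <- geom$station_diameter * 10 / 2 * 1e-3
  fine <- seq(0, max(s_st), by = min(1e-3, h / 2))
  clf <- sapply(1:3, function(j) stats::approx(s_st, cl[, j], xout = fine)$y)
  rf <- stats::approx(s_st, r_st, xout = fine)$y
  tangents <- geom$tangents
  if (is.null(inlet_len_mm)) inlet_len_mm <- 3 * h_mm
  if (is.null(outlet_len_mm)) outlet_len_mm <- 3 * h_mm
  rmax <- max(rf)
  lo <- apply(clf, 2L, min) - rmax - 2 * h
  hi <- apply(clf, 2L, max) + rmax + 2 * h
  dims <- pmax(as.integer(ceiling((hi - lo) / h)), 3L)
  origin <- lo
  ax <- lapply(1:3, function(j) origin[j] + (seq_len(dims[j]) - 0.5) * h)
  # tube queries on the cell grid and the three face grids
  qc <- tube_query(ax[[1L]], ax[[2L]], ax[[3L]], clf, rf, fine, rmax, h)
  axu <- lapply(1:3, function(j)
    origin[j] + (seq_len(dims[j] + (j == 1L)) - ifelse(j == 1L, 1, 0.5)) * h)
  axv <- lapply(1:3, function(j)
    origin[j] + (seq_len(dims[j] + (j == 2L)) - ifelse(j == 2L, 1, 0.5)) * h)
  axw <- lapply(1:3, function(j)
    origin[j] + (seq_len(dims[j] + (j == 3L)) - ifelse(j == 3L, 1, 0.5)) * h)
  qf <- list(tube_query(axu[[1L]], axu[[2L]], axu[[3L]], clf, rf, fine, rmax, h),
             tube_query(axv[[1L]], axv[[2L]], axv[[3L]], clf, rf, fine, rmax, h),
             tube_query(axw[[1L]], axw[[2L]], axw[[3L]], clf, rf, fine, rmax, h))
  L_tot <- max(fine)
  inlet_s <- inlet_len_mm * 1e-3
  outlet_s <- L_tot - outlet_len_mm * 1e-3
  SOLID <- 0L; FREE <- 1L; INLET <- 2L; OUTLET <- 3L
  ctype <- array(SOLID, dims)
  ctype[qc$sdf < 0] <- FREE
  ctype[qc$sdf < 0 & qc$s < inlet_s] <- INLET
  ctype[qc$sdf < 0 & qc$s > outlet_s] <- OUTLET
  # keep only the largest connected fluid component (6-connectivity)
  ctype <- keep_largest_fluid(ctype, dims)
  # face classification per component
  comp <- vector("list", 3L)
  for (d in 1:3) {
    fd <- dims; fd[d] <- fd[d] + 1L
    sdf_f <- qf[[d]]$sdf
    cl_idx <- face_cell_indices(fd, dims, d)
    tl <- ctype[cl_idx$left]; tr <- ctype[cl_idx$right]
    tl[is.na(tl)] <- SOLID; tr[is.na(tr)] <- SOLID
    ft <- integer(prod(fd))                         # 0 wall
    open <- tl != SOLID & tr != SOLID & as.vector(sdf_f) < 0
    ft[open & (tl == INLET | tr == INLET)] <- 2L    # inlet (prescribed)
    ft[open & ft == 0L & (tl == INLET | tr == INLET)] <- 2L
    ft[open & tl != INLET & tr != INLET] <- 1L      # active
    comp[[d]] <- list(dims = fd, ftype = ft, sdf = sdf_f,
                      s = qf[[d]]$s, dist = qf[[d]]$dist,
                      left = cl_idx$left, right = cl_idx$right)
  }
  # drop FREE cells with no active face (isolated pockets)
  repeat {
    nact <- array(0L, dims)
    for (d in 1:3) {
      fd <- comp[[d]]$dims
      act <- array(comp[[d]]$ftype == 1L, fd)
      nact <- nact + face_sum_to_cells(act, dims, d)
    }
    drop <- ctype == FREE & nact == 0L
    if (!any(drop)) break
    ctype[drop] <- SOLID
    for (d in 1:3) {
      tl <- ctype[comp[[d]]$left]; tr <- ctype[comp[[d]]$right]
      tl[is.na(tl)] <- SOLID; tr[is.na(tr)] <- SOLID
      bad <- comp[[d]]$ftype != 0L & (tl == SOLID | tr == SOLID)
      comp[[d]]$ftype[bad] <- 0L
    }
  }
  cell_index <- which(ctype != SOLID)
  free_index <- which(ctype == FREE)
  if (!length(free_index)) stop("no free fluid cells; geometry too small for the grid")
  # per-fluid-cell geometry samples
  s_cell <- qc$s[cell_index]
  dist_cell <- qc$dist[cell_index]
  r_cell <- stats::approx(fine, rf, xout = s_cell, rule = 2L)$y
  tan_cell <- t(sapply(1:3, function(j)
    stats::approx(s_st, tangents[, j], xout = pmin(s_cell, max(s_st)), rule = 2L)$y))
  tan_cell <- t(tan_cell) / sqrt(colSums(tan_cell^2))
  cc <- arrayInd(cell_index, dims)
  cell_xyz <- cbind(origin[1L] + (cc[, 1L] - 0.5) * h,
                    origin[2L] + (cc[, 2L] - 0.5) * h,
                    origin[3L] + (cc[, 3L] - 0.5) * h)
  near <- sapply(1:3, function(j) stats::approx(fine, clf[, j], xout = s_cell)$y)
  radial <- cell_xyz - near
  rl <- sqrt(rowSums(radial^2)); rl[rl == 0] <- 1
  radial <- radial / rl
  # operators
  for (d in 1:3) comp[[d]] <- build_component_ops(comp[[d]], d, theta_min, h)
  # fully developed (parabolic) inlet profile prefactor per inlet face:
  # face value = u_mean * 2 * (1 - (rho_d / r)^2) * tangent_d
  for (d in 1:3) {
    ii <- comp[[d]]$inlet_faces
    if (length(ii)) {
      s_f <- pmin(comp[[d]]$s[ii], max(s_st))
      r_f <- stats::approx(fine, rf, xout = s_f, rule = 2L)$y
      rho_d <- pmin(comp[[d]]$dist[ii] / r_f, 1)
      t_d <- stats::approx(s_st, tangents[, d], xout = s_f, rule = 2L)$y
      comp[[d]]$inlet_pref <- 2 * (1 - rho_d^2) * t_d
    } else comp[[d]]$inlet_pref <- numeric(0)
  }
  pois <- build_poisson(ctype, dims, comp, h)
  div_idx <- build_div_indices(free_index, dims, comp)
  adv_idx <- lapply(1:3, function(d) build_advection_indices(comp, d))
  dom <- structure(list(
    h = h, dims = dims, origin = origin, ctype = ctype,
    cell_index = cell_index, free_index = free_index,
    s_cell = s_cell, dist_cell = dist_cell, r_cell = r_cell,
    tangent_cell = tan_cell, radial_cell = radial, cell_xyz = cell_xyz,
    comp = comp, poisson = pois, div_idx = div_idx, adv_idx = adv_idx,
    s_total = L_tot, inlet_s = inlet_s, outlet_s = outlet_s,
    mean_diameter = d_mean * 1e-3, theta_min = theta_min,
    fine_s = fine, fine_r = rf, geom = geom), class = "fluid_domain")
  dom
}

#' @export
print.fluid_domain <- function(x, ...) {
  cat(sprintf("<fluid_domain> grid %d x %d x %d, h = %.3g mm, %d fluid cells (%d free)\n",
              x$dims[1L], x$dims[2L], x$dims[3L], x$h * 1e3,
              length(x$cell_index), length(x$free_index)))
  invisible(x)
}

# distance and arclength of the nearest tube centerline point for every grid
# node, computed segment-by-segment over the segment's bounding sub-block
tube_query <- function(xs, ys, zs, cl, r, s_fine, rmax, h) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  d2 <- array(Inf, c(nx, ny, nz))
  sa <- array(NA_real_, c(nx, ny, nz))
  pad <- rmax + 2 * h
  nseg <- nrow(cl) - 1L
  step <- max(1L, floor(2e-3 / max(diff(s_fine))))   # ~2 mm chunks
  k <- 1L
  while (k <= nseg) {
    k2 <- min(k + step, nseg + 1L)
    seg <- cl[k:k2, , drop = FALSE]
    blo <- apply(seg, 2L, min) - pad
    bhi <- apply(seg, 2L, max) + pad
    ix <- which(xs >= blo[1L] & xs <= bhi[1L])
    iy <- which(ys >= blo[2L] & ys <= bhi[2L])
    iz <- which(zs >= blo[3L] & zs <= bhi[3L])
    if (length(ix) && length(iy) && length(iz)) {
      gx <- xs[ix]; gy <- ys[iy]; gz <- zs[iz]
      nb <- c(length(ix), length(iy), length(iz))
      X <- array(gx, nb)
      Y <- aperm(array(gy, c(nb[2L], nb[1L], nb[3L])), c(2L, 1L, 3L))
      Z <- aperm(array(gz, c(nb[3L], nb[1L], nb[2L])), c(2L, 3L, 1L))
      bd2 <- array(Inf, nb); bs <- array(0, nb)
      for (q in k:(k2 - 1L)) {
        a <- cl[q, ]; b <- cl[q + 1L, ]
        ab <- b - a; len2 <- sum(ab^2)
        if (len2 == 0) next
        t_ <- ((X - a[1L]) * ab[1L] + (Y - a[2L]) * ab[2L] + (Z - a[3L]) * ab[3L]) / len2
        t_[t_ < 0] <- 0; t_[t_ > 1] <- 1
        dd <- (X - (a[1L] + t_ * ab[1L]))^2 + (Y - (a[2L] + t_ * ab[2L]))^2 +
          (Z - (a[3L] + t_ * ab[3L]))^2
        upd <- dd < bd2
        bd2[upd] <- dd[upd]
        bs[upd] <- s_fine[q] + t_[upd] * (s_fine[q + 1L] - s_fine[q])
      }
      old <- d2[ix, iy, iz]
      upd <- bd2 < old
      old[upd] <- bd2[upd]
      d2[ix, iy, iz] <- old
      sold <- sa[ix, iy, iz]
      sold[upd] <- bs[upd]
      sa[ix, iy, iz] <- sold
    }
    k <- k2
  }
  dist <- sqrt(d2)
  rloc <- array(stats::approx(s_fine, r, xout = as.vector(sa), rule = 2L)$y,
                dim(dist))
  rloc[is.na(rloc)] <- 0
  sdf <- dist - rloc
  sdf[!is.finite(sdf)] <- 1
  list(dist = dist, s = sa, sdf = sdf)
}

# linear indices (into the cell grid) of the two cells adjoining each face;
# NA where the neighbour falls outside the grid
face_cell_indices <- function(fd, dims, d) {
  idx <- arrayInd(seq_len(prod(fd)), fd)
  left <- idx; right <- idx
  left[, d] <- left[, d] - 1L
  ok_l <- left[, d] >= 1L
  ok_r <- right[, d] <= dims[d]
  lin <- function(m, ok) {
    out <- rep(NA_integer_, nrow(m))
    out[ok] <- m[ok, 1L] + (m[ok, 2L] - 1L) * dims[1L] +
      (m[ok, 3L] - 1L) * dims[1L] * dims[2L]
    out
  }
  list(left = lin(left, ok_l), right = lin(right, ok_r))
}

# per-cell count of flagged faces along axis d
face_sum_to_cells <- function(face_arr, dims, d) {
  if (d == 1L) face_arr[seq_len(dims[1L]), , , drop = FALSE] +
    face_arr[seq_len(dims[1L]) + 1L, , , drop = FALSE]
  else if (d == 2L) face_arr[, seq_len(dims[2L]), , drop = FALSE] +
    face_arr[, seq_len(dims[2L]) + 1L, , drop = FALSE]
  else face_arr[, , seq_len(dims[3L]), drop = FALSE] +
    face_arr[, , seq_len(dims[3L]) + 1L, drop = FALSE]
}

keep_largest_fluid <- function(ctype, dims) {
  fl <- which(ctype != 0L)
  if (!length(fl)) stop("no fluid cells inside the grid")
  pos <- arrayInd(fl, dims)
  id <- seq_along(fl)
  map <- array(0L, dims)
  map[fl] <- id
  edges <- NULL
  for (d in 1:3) {
    nb <- pos; nb[, d] <- nb[, d] + 1L
    ok <- nb[, d] <= dims[d]
    lin <- nb[ok, 1L] + (nb[ok, 2L] - 1L) * dims[1L] +
      (nb[ok, 3L] - 1L) * dims[1L] * dims[2L]
    hit <- map[lin] > 0L
    if (any(hit)) edges <- cbind(edges, rbind(id[ok][hit], map[lin][hit]))
  }
  if (is.null(edges)) return(ctype)
  g <- igraph::make_graph(as.vector(edges), n = length(fl), directed = FALSE)
  cmp <- igraph::components(g)
  keep <- cmp$membership == which.max(cmp$csize)
  ctype[fl[!keep]] <- 0L
  ctype
}

# sparse viscous Laplacian over active faces + coupling to inlet faces,
# with Shortley-Weller sub-cell wall distances
build_component_ops <- function(cp, d, theta_min, h) {
  fd <- cp$dims
  active <- which(cp$ftype == 1L)
  inlet <- which(cp$ftype == 2L)
  amap <- integer(prod(fd)); amap[active] <- seq_along(active)
  imap <- integer(prod(fd)); imap[inlet] <- seq_along(inlet)
  na <- length(active)
  pos <- arrayInd(active, fd)
  sdf_v <- as.vector(cp$sdf)
  tripI <- list(); tripJ <- list(); tripX <- list()
  ctripI <- list(); ctripJ <- list(); ctripX <- list()
  diag_acc <- numeric(na)
  strides <- c(1L, fd[1L], fd[1L] * fd[2L])
  for (ax in 1:3) {
    st <- strides[ax]
    nb_m <- active - st
    nb_p <- active + st
    in_m <- pos[, ax] > 1L
    in_p <- pos[, ax] < fd[ax]
    cls_m <- integer(na); cls_p <- integer(na)      # 0 wall, 1 active, 2 inlet
    cls_m[in_m] <- cp$ftype[nb_m[in_m]]
    cls_p[in_p] <- cp$ftype[nb_p[in_p]]
    th <- function(nb, inr) {
      t_ <- rep(1, na)
      wall <- rep(TRUE, na)
      wall[inr] <- cp$ftype[nb[inr]] == 0L
      i <- which(wall & inr)
      if (length(i)) {
        sp <- sdf_v[active[i]]; sn <- sdf_v[nb[i]]
        tt <- ifelse(sn > sp, sp / (sp - sn), 1)
        t_[i] <- pmin(pmax(tt, theta_min), 1)
      }
      t_[wall & !inr] <- 1
      list(theta = t_, wall = wall)
    }
    tm <- th(nb_m, in_m); tp <- th(nb_p, in_p)
    a_m <- tm$theta; a_p <- tp$theta
    c_m <- 2 / (a_m * (a_m + a_p)) / h^2
    c_p <- 2 / (a_p * (a_m + a_p)) / h^2
    diag_acc <- diag_acc - 2 / (a_m * a_p) / h^2
    for (side in 1:2) {
      nb <- if (side == 1L) nb_m else nb_p
      cls <- if (side == 1L) cls_m else cls_p
      cf <- if (side == 1L) c_m else c_p
      ia <- which(cls == 1L)
      if (length(ia)) {
        tripI <- c(tripI, list(seq_len(na)[ia]))
        tripJ <- c(tripJ, list(amap[nb[ia]]))
        tripX <- c(tripX, list(cf[ia]))
      }
      ii <- which(cls == 2L)
      if (length(ii)) {
        ctripI <- c(ctripI, list(seq_len(na)[ii]))
        ctripJ <- c(ctripJ, list(imap[nb[ii]]))
        ctripX <- c(ctripX, list(cf[ii]))
      }
    }
  }
  L <- Matrix::sparseMatrix(i = c(unlist(tripI), seq_len(na)),
                            j = c(unlist(tripJ), seq_len(na)),
                            x = c(unlist(tripX), diag_acc),
                            dims = c(na, na))
  C <- if (length(inlet))
    Matrix::sparseMatrix(i = unlist(ctripI), j = unlist(ctripJ),
                         x = unlist(ctripX), dims = c(na, length(inlet)))
  else Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(na, 0L))
  cp$active <- active; cp$inlet_faces <- inlet
  cp$L <- L; cp$C <- C
  cp$max_diag <- max(-diag_acc)
  cp
}

# pressure Poisson system over FREE cells: M p = (rho/dt) div(u*) - b_out*p_out
build_poisson <- function(ctype, dims, comp, h) {
  FREE <- 1L; OUTLET <- 3L
  free <- which(ctype == FREE)
  nfree <- length(free)
  pmap <- integer(prod(dims)); pmap[free] <- seq_len(nfree)
  pos <- arrayInd(free, dims)
  strides <- c(1L, dims[1L], dims[1L] * dims[2L])
  I <- list(); J <- list(); X <- list()
  diag_acc <- numeric(nfree)
  out_coef <- numeric(nfree)
  for (ax in 1:3) {
    fd <- comp[[ax]]$dims
    fstr <- c(1L, fd[1L], fd[1L] * fd[2L])
    face_lin_m <- pos[, 1L] + (pos[, 2L] - 1L) * fstr[2L] + (pos[, 3L] - 1L) * fstr[3L]
    face_lin_p <- face_lin_m + fstr[ax]
    for (side in 1:2) {
      flin <- if (side == 1L) face_lin_m else face_lin_p
      open <- comp[[ax]]$ftype[flin] == 1L          # active face
      nb <- free + (if (side == 1L) -strides[ax] else strides[ax])
      inb <- if (side == 1L) pos[, ax] > 1L else pos[, ax] < dims[ax]
      t_nb <- integer(nfree)
      t_nb[inb] <- ctype[nb[inb]]
      isfree <- open & inb & t_nb == FREE
      isout <- open & inb & t_nb == OUTLET
      diag_acc <- diag_acc - (open & inb & (t_nb == FREE | t_nb == OUTLET)) / h^2
      if (any(isfree)) {
        I <- c(I, list(which(isfree)))
        J <- c(J, list(pmap[nb[isfree]]))
        X <- c(X, list(rep(1 / h^2, sum(isfree))))
      }
      out_coef <- out_coef + isout / h^2
    }
  }
  M <- Matrix::sparseMatrix(i = c(unlist(I), seq_len(nfree)),
                            j = c(unlist(J), seq_len(nfree)),
                            x = c(unlist(X), diag_acc),
                            dims = c(nfree, nfree))
  chol <- Matrix::Cholesky(-M, LDL = FALSE, perm = TRUE)
  list(free = free, pmap = pmap, chol = chol, out_coef = out_coef)
}

# precomputed index vectors for upwind advection at the active faces of
# component d: along-axis neighbours in the same face grid, and the four
# surrounding faces of each cross component for the advecting-velocity
# average
build_advection_indices <- function(comp, d) {
  cp <- comp[[d]]
  fd <- cp$dims
  active <- cp$active
  pos <- arrayInd(active, fd)
  strides <- c(1L, fd[1L], fd[1L] * fd[2L])
  ax <- lapply(1:3, function(a)
    list(m = active - strides[a], p = active + strides[a]))
  unit <- diag(3L)
  cross <- list()
  for (e in setdiff(1:3, d)) {
    fe <- comp[[e]]$dims
    lin_e <- function(p) p[, 1L] + (p[, 2L] - 1L) * fe[1L] +
      (p[, 3L] - 1L) * fe[1L] * fe[2L]
    cellL <- pos; cellL[, d] <- cellL[, d] - 1L   # cell coords of both sides
    cellR <- pos
    cross[[as.character(e)]] <- list(
      comp = e,
      i1 = lin_e(cellL), i2 = lin_e(cellL + matrix(unit[e, ], nrow(pos), 3L,
                                                   byrow = TRUE)),
      i3 = lin_e(cellR), i4 = lin_e(cellR + matrix(unit[e, ], nrow(pos), 3L,
                                                   byrow = TRUE)))
  }
  list(ax = ax, cross = cross)
}

# linear face indices of the 6 faces around each FREE cell, for divergence
build_div_indices <- function(free_index, dims, comp) {
  pos <- arrayInd(free_index, dims)
  out <- vector("list", 3L)
  for (ax in 1:3) {
    fd <- comp[[ax]]$dims
    fstr <- c(1L, fd[1L], fd[1L] * fd[2L])
    m <- pos[, 1L] + (pos[, 2L] - 1L) * fstr[2L] + (pos[, 3L] - 1L) * fstr[3L]
    out[[ax]] <- list(m = m, p = m + fstr[ax])
  }
  out
}
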