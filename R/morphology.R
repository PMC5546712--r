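# molecules per (nM * um^3)
COUNT_PER_NM_UM3 <- 0.602214076

REGIONS <- c("dend_cyt", "dend_sub", "spine_neck", "spine_head", "psd")

# localization -> regions a species may occupy
loc_regions <- function(loc) {
  switch(loc,
         cyt  = REGIONS,
         sub  = c("dend_sub", "spine_head"),
         psd  = "psd",
         head = "spine_head",
         stop("unknown localization: ", loc))
}

#' Dendrite + spine geometry specification
#'
#' Dimensions in um. The default spine shape (head 0.5 x 0.5 cylinder, neck
#' 0.2 x 0.5) is a typical CA1 mushroom spine; the dendrite defaults follow
#' the single-spine morphology (2 um long, 0.6 um diameter).
#'
#' @param dendrite_length,dendrite_diameter cylinder dimensions (um).
#' @param spine_positions axial positions of spine attachment (um).
#' @param head_diameter,head_length,neck_diameter,neck_length spine shape (um).
#' @param psd_thickness thickness of the PSD voxel at the spine tip (um).
#' @return object of class `geometry_spec`.
#' @export
geometry_spec <- function(dendrite_length = 2, dendrite_diameter = 0.6,
                          spine_positions = dendrite_length / 2,
                          head_diameter = 0.5, head_length = 0.5,
                          neck_diameter = 0.2, neck_length = 0.5,
                          psd_thickness = 0.1) {
  if (dendrite_length <= 0 || dendrite_diameter <= 0)
    stop("dendrite dimensions must be positive")
  if (length(spine_positions) &&
      (any(spine_positions < 0) || any(spine_positions > dendrite_length)))
    stop("spines must lie within the dendrite length")
  if (length(spine_positions) &&
      (head_diameter <= 0 || neck_diameter <= 0 ||
       head_length <= psd_thickness || neck_length <= 0))
    stop("spine dimensions must be positive (head longer than the PSD layer)")
  structure(list(dendrite_length = dendrite_length,
                 dendrite_diameter = dendrite_diameter,
                 spine_positions = sort(spine_positions),
                 head_diameter = head_diameter, head_length = head_length,
                 neck_diameter = neck_diameter, neck_length = neck_length,
                 psd_thickness = psd_thickness),
            class = "geometry_spec")
}

#' @export
print.geometry_spec <- function(x, ...) {
  cat("<geometry_spec> dendrite ", x$dendrite_length, " x ",
      x$dendrite_diameter, " um, ", length(x$spine_positions),
      " spine(s)\n", sep = "")
  invisible(x)
}

#' Build a voxel mesh from a geometry
#'
#' The dendrite is cut into axial slices of length `resolution`; each slice
#' is split vertically into a top submembrane voxel, a cytosolic core, and a
#' bottom submembrane voxel, giving two-dimensional (axial + radial) diffusion
#' in the dendrite. Each spine is a one-dimensional chain: neck voxel(s), a
#' head voxel, and a PSD voxel at the tip. Outer boundaries are reflective;
#' the spine-dendrite coupling is proportional to the neck cross-sectional
#' area. Couplings store the geometric factor `A/d` (contact area over
#' center distance); a species with diffusion constant D exchanges at rate
#' `D * A / (d * V_source)` per second.
#'
#' @param g a [geometry_spec()].
#' @param resolution axial voxel size (um); must resolve the spine neck.
#' @param submembrane_thickness thickness of the submembrane layer (um).
#' @return object of class `voxel_mesh` with `voxels` and `couplings`.
#' @export
build_mesh <- function(g, resolution = 0.5, submembrane_thickness = 0.1) {
  stopifnot(inherits(g, "geometry_spec"))
  if (length(g$spine_positions) && resolution > g$neck_length + 1e-12)
    stop("resolution too coarse to represent the spine neck (",
         resolution, " > ", g$neck_length, " um)")
  if (2 * submembrane_thickness >= g$dendrite_diameter)
    stop("submembrane layers exceed dendrite diameter")
  nz <- max(1L, round(g$dendrite_length / resolution))
  dz <- g$dendrite_length / nz
  area <- pi * (g$dendrite_diameter / 2)^2
  v_slice <- area * dz
  f_sub <- submembrane_thickness / g$dendrite_diameter
  vox <- list(); cpl <- list()
  add_vox <- function(region, volume, spine = NA_integer_, x = NA_real_) {
    vox[[length(vox) + 1L]] <<- data.frame(
      id = length(vox) + 1L, region = region, volume = volume,
      spine = spine, x = x, stringsAsFactors = FALSE)
    length(vox)
  }
  add_cpl <- function(i, j, A, d)
    cpl[[length(cpl) + 1L]] <<- data.frame(i = i, j = j, A = A, d = d)

  # dendrite: per slice ids [top, cyt, bottom]
  ids <- matrix(0L, nrow = nz, ncol = 3)
  for (s in seq_len(nz)) {
    x <- (s - 0.5) * dz
    ids[s, 1] <- add_vox("dend_sub", v_slice * f_sub, x = x)
    ids[s, 2] <- add_vox("dend_cyt", v_slice * (1 - 2 * f_sub), x = x)
    ids[s, 3] <- add_vox("dend_sub", v_slice * f_sub, x = x)
    # vertical couplings within the slice
    d_vert <- g$dendrite_diameter / 2
    A_vert <- v_slice / g$dendrite_diameter  # slab contact area ~ V/height
    add_cpl(ids[s, 1], ids[s, 2], A_vert, d_vert)
    add_cpl(ids[s, 2], ids[s, 3], A_vert, d_vert)
    if (s > 1) for (k in 1:3) add_cpl(ids[s - 1, k], ids[s, k],
                                      area * c(f_sub, 1 - 2 * f_sub, f_sub)[k],
                                      dz)
  }

  # spines: neck chain -> head -> psd, attached to nearest top submembrane
  n_spine <- length(g$spine_positions)
  for (sp in seq_len(n_spine)) {
    x <- g$spine_positions[sp]
    slice <- min(nz, max(1L, ceiling(x / dz)))
    attach_id <- ids[slice, 1]
    a_neck <- pi * (g$neck_diameter / 2)^2
    n_neck <- max(1L, round(g$neck_length / resolution))
    dzn <- g$neck_length / n_neck
    prev <- attach_id; prev_d <- submembrane_thickness / 2
    for (k in seq_len(n_neck)) {
      id <- add_vox("spine_neck", a_neck * dzn, spine = sp, x = x)
      add_cpl(prev, id, a_neck, prev_d + dzn / 2)
      prev <- id; prev_d <- dzn / 2
    }
    a_head <- pi * (g$head_diameter / 2)^2
    h_body <- g$head_length - g$psd_thickness
    id_head <- add_vox("spine_head", a_head * h_body, spine = sp, x = x)
    add_cpl(prev, id_head, a_neck, prev_d + h_body / 2)
    id_psd <- add_vox("psd", a_head * g$psd_thickness, spine = sp, x = x)
    add_cpl(id_head, id_psd, a_head, (h_body + g$psd_thickness) / 2)
  }

  mesh <- structure(list(voxels = do.call(rbind, vox),
                         couplings = if (length(cpl)) do.call(rbind, cpl)
                                     else data.frame(i = integer(0),
                                                     j = integer(0),
                                                     A = numeric(0),
                                                     d = numeric(0)),
                         geometry = g, resolution = resolution),
                    class = "voxel_mesh")
  mesh
}

#' @export
print.voxel_mesh <- function(x, ...) {
  cat("<voxel_mesh> ", nrow(x$voxels), " voxels, ",
      nrow(x$couplings), " couplings, total volume ",
      signif(sum(x$voxels$volume), 4), " um^3\n", sep = "")
  print(table(x$voxels$region))
  invisible(x)
}

#' Geometric volume implied by the geometry spec (um^3)
#' @param g a [geometry_spec()].
#' @export
geometry_volume <- function(g) {
  v <- pi * (g$dendrite_diameter / 2)^2 * g$dendrite_length
  n <- length(g$spine_positions)
  if (n) v <- v + n * (pi * (g$neck_diameter / 2)^2 * g$neck_length +
                       pi * (g$head_diameter / 2)^2 * g$head_length)
  v
}

#' Per-region initial molecule counts
#'
#' Anchored species are placed only in the voxels of their declared region;
#' diffusible species are distributed over all voxels at their initial
#' concentration. Counts are rounded to integers after applying the model's
#' volume factor.
#'
#' @param mesh a [build_mesh()] result.
#' @param m a `sig_model`.
#' @return matrix species x region of molecule counts.
#' @export
region_totals <- function(mesh, m) {
  vr <- tapply(mesh$voxels$volume, factor(mesh$voxels$region, REGIONS), sum,
               default = 0)
  out <- matrix(0, nrow(m$species), length(REGIONS),
                dimnames = list(m$species$name, REGIONS))
  for (i in seq_len(nrow(m$species))) {
    regs <- loc_regions(m$species$loc[i])
    have <- regs[vr[regs] > 0]
    if (m$species$init[i] > 0 && !length(have))
      stop("anchored species '", m$species$name[i],
           "' has no voxels of its region in this mesh")
    out[i, have] <- round(m$species$init[i] * vr[have] *
                          COUNT_PER_NM_UM3 * m$volume_factor)
  }
  out
}

#' Export the mesh as a flat table
#' @param mesh a `voxel_mesh`.
#' @return data.frame (voxel id, region, volume, spine, neighbors).
#' @export
mesh_table <- function(mesh) {
  nb <- vapply(mesh$voxels$id, function(i) {
    n <- c(mesh$couplings$j[mesh$couplings$i == i],
           mesh$couplings$i[mesh$couplings$j == i])
    paste(sort(n), collapse = ";")
  }, "")
  cbind(mesh$voxels, neighbors = nb)
}

#' Reduce a mesh to well-mixed compartments
#'
#' Groups voxels into compartments for the deterministic compartmental mode:
#' one compartment per (spine, sub-structure) -- spine head (with its PSD
#' merged in) and spine neck per spine -- plus dendrite submembrane and
#' dendrite cytosol. Inter-compartment exchange factors are the summed `A/d`
#' of the voxel couplings crossing the compartment boundary.
#'
#' @param mesh a `voxel_mesh`.
#' @return object of class `sig_compartments` with `volume`, `region` (region
#'   composition per compartment) and `exchange` (i, j, Ad).
#' @export
compartments <- function(mesh) {
  v <- mesh$voxels
  key <- ifelse(v$region %in% c("spine_head", "psd"),
                paste0("head", v$spine),
                ifelse(v$region == "spine_neck", paste0("neck", v$spine),
                       v$region))
  comp_names <- unique(key)
  comp_of <- match(key, comp_names)
  vol <- tapply(v$volume, comp_of, sum)
  # region volumes inside each compartment (concentration bookkeeping)
  regvol <- matrix(0, length(comp_names), length(REGIONS),
                   dimnames = list(comp_names, REGIONS))
  for (k in seq_len(nrow(v)))
    regvol[comp_of[k], v$region[k]] <- regvol[comp_of[k], v$region[k]] +
      v$volume[k]
  cc <- mesh$couplings
  ci <- comp_of[cc$i]; cj <- comp_of[cc$j]
  cross <- ci != cj
  ex <- data.frame(i = ci[cross], j = cj[cross], Ad = cc$A[cross] / cc$d[cross])
  if (nrow(ex)) {
    keyp <- paste(pmin(ex$i, ex$j), pmax(ex$i, ex$j))
    agg <- tapply(ex$Ad, keyp, sum)
    ij <- do.call(rbind, strsplit(names(agg), " "))
    ex <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                     Ad = as.numeric(agg))
  }
  spine_of <- tapply(v$spine, comp_of, function(s) {
    s <- s[!is.na(s)]; if (length(s)) s[1] else NA_integer_
  })
  structure(list(names = comp_names, volume = as.numeric(vol),
                 region_volume = regvol, exchange = ex,
                 spine = as.integer(spine_of)),
            class = "sig_compartments")
}

#' @export
print.sig_compartments <- function(x, ...) {
  cat("<sig_compartments> ", length(x$names), " compartments: ",
      paste(x$names, collapse = ", "), "\n", sep = "")
  invisible(x)
}
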