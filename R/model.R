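#' Build a subject-specific rigid-segment musculoskeletal model
#'
#' Constructs the lower-body model used throughout the pipeline: pelvis,
#' left/right thigh, shank, talus and foot (nine segments) plus one lumped
#' head-arms-trunk (HAT) segment welded to the pelvis. Joints: 3-DOF ball
#' hips, hinge knees, hinge ankles and subtalar joints. Segment lengths
#' derive from the subject's stature, hip breadth and femur length; masses
#' and inertias from documented anthropometric fractions of body mass, so
#' total model mass equals body mass exactly. Muscle elements (12-element
#' gluteus medius/minimus/maximus fans per side plus the remaining major
#' hip/knee/ankle groups; 118 elements in total) attach at sites placed
#' parametrically by the hip shape variant, with maximum strengths taken
#' from published order-of-magnitude values scaled by body mass.
#'
#' Axis convention: X = direction of travel, Y = mediolateral (left
#' positive), Z = vertical. All joint angles are zero in upright standing.
#'
#' @param variant a [hip_shape_params()].
#' @param subject one-row tibble from [generate_cohort()].
#' @return object of class `skeleton_model`.
#' @export
build_subject_model <- function(variant, subject) {
  if (!inherits(variant, "hip_shape_params")) {
    stop("`variant` must be a `hip_shape_params` object", call. = FALSE)
  }
  subject <- as.list(subject)
  M <- subject$body_mass
  st <- subject$stature
  hb <- subject$hip_breadth
  fl <- subject$femur_length
  sl <- 0.246 * st
  foot_len <- 0.152 * st
  talus_h <- 0.04
  hat_len <- 0.47 * st
  d <- pelvis_dims(variant, hb)

  seg <- function(name, parent, joint_location, rotations, mass, com, rg,
                  length) {
    list(name = name, parent = parent, joint_location = joint_location,
         rotations = rotations, mass = mass, com = com,
         inertia = diag(mass * rg^2), length = length)
  }
  ax <- list(x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  lat <- c(r = -1, l = 1)  # lateral-to-medial sign bookkeeping: +Y is left

  segments <- list(
    pelvis = seg("pelvis", NA, NULL,
                 list(list(axis = ax$z, coord = "pelvis_rotation"),
                      list(axis = ax$x, coord = "pelvis_list"),
                      list(axis = ax$y, coord = "pelvis_tilt")),
                 0.112 * M, c(-0.02, 0, 0.02),
                 c(0.31, 0.31, 0.30) * hb, hb),
    hat = seg("hat", "pelvis", c(-0.01, 0, 0.09), list(),
              0.4908 * M, c(0.01, 0, 0.35 * hat_len),
              c(0.35, 0.35, 0.16) * hat_len, hat_len)
  )
  for (s in c("r", "l")) {
    la <- lat[[s]]  # +1 left, -1 right: Y coordinate sign of the side
    segments[[paste0("thigh_", s)]] <- seg(
      paste0("thigh_", s), "pelvis", c(0, la * hb / 2, 0),
      list(list(axis = -ax$y, coord = paste0("hip_flexion_", s)),
           list(axis = -la * ax$x, coord = paste0("hip_adduction_", s)),
           list(axis = -la * ax$z, coord = paste0("hip_rotation_", s))),
      0.1416 * M, c(0, 0, -0.41 * fl), c(0.329, 0.329, 0.149) * fl, fl)
    segments[[paste0("shank_", s)]] <- seg(
      paste0("shank_", s), paste0("thigh_", s), c(0, 0, -fl),
      list(list(axis = ax$y, coord = paste0("knee_flexion_", s))),
      0.0433 * M, c(0, 0, -0.44 * sl), c(0.251, 0.251, 0.103) * sl, sl)
    segments[[paste0("talus_", s)]] <- seg(
      paste0("talus_", s), paste0("shank_", s), c(0, 0, -sl),
      list(list(axis = -ax$y, coord = paste0("ankle_flexion_", s))),
      0.002 * M, c(0, 0, -0.02), c(0.02, 0.02, 0.02), talus_h)
    segments[[paste0("foot_", s)]] <- seg(
      paste0("foot_", s), paste0("talus_", s), c(0, 0, -talus_h),
      list(list(axis = -la * ax$x, coord = paste0("subtalar_", s))),
      0.0117 * M, c(0.3 * foot_len - 0.05 * st / 1.7, 0, -0.03),
      c(0.25, 0.25, 0.12) * foot_len, foot_len)
  }

  coord_names <- c("pelvis_x", "pelvis_y", "pelvis_z",
                   "pelvis_rotation", "pelvis_list", "pelvis_tilt",
                   unlist(lapply(c("r", "l"), function(s) paste0(
                     c("hip_flexion_", "hip_adduction_", "hip_rotation_",
                       "knee_flexion_", "ankle_flexion_", "subtalar_"), s))))

  model <- structure(list(
    segments = segments,
    order = names(segments),
    coord_names = coord_names,
    muscles = build_muscles(variant, subject, d, fl, sl, foot_len),
    markers = build_marker_set(subject, d, fl, sl, foot_len, hat_len),
    dims = list(shank_length = sl, foot_length = foot_len,
                talus_height = talus_h, hat_length = hat_len),
    subject = tibble::as_tibble(subject),
    variant = variant
  ), class = "skeleton_model")
  attr(model, "path_cache") <- path_cache(model)
  model
}

#' @export
print.skeleton_model <- function(x, ...) {
  cat("<skeleton_model> ", length(x$segments), " segments, ",
      nrow(x$muscles), " muscle elements, variant: ", x$variant$variant,
      "\n", sep = "")
  invisible(x)
}

# Group strengths in newton per kilogram body mass, split equally over the
# group's elements. Order-of-magnitude values from published lower-limb
# models; the pipeline's inferences are comparative across variants, which
# share these strengths exactly.
muscle_strength_table <- function() {
  tibble::tribble(
    ~group, ~n_elements, ~strength_per_kg,
    "gluteus_medius",    12L, 34,
    "gluteus_minimus",   12L, 12,
    "gluteus_maximus",   12L, 26,
    "iliopsoas",          3L, 29,
    "adductors",          4L, 25,
    "hamstrings",         3L, 30,
    "rectus_femoris",     1L, 15,
    "vasti",              3L, 50,
    "gastrocnemius",      2L, 29,
    "soleus",             2L, 47,
    "tibialis_anterior",  2L, 12,
    "deep_rotators",      2L, 7,
    "pectineus",          2L, 10,
    "tensor_fasciae_latae", 1L, 4
  )
}

build_muscles <- function(variant, subject, d, fl, sl, foot_len) {
  M <- subject$body_mass
  hb <- d$hb
  nl <- d$neck_length
  strengths <- muscle_strength_table()

  out <- list()
  add <- function(group, side, idx, path) {
    row <- strengths[strengths$group == group, ]
    out[[length(out) + 1]] <<- tibble::tibble(
      element = sprintf("%s_%s%02d", group, side, idx),
      group = group, side = side,
      max_strength = row$strength_per_kg * M / row$n_elements,
      path = list(path)
    )
  }
  pt <- function(segment, p) list(segment = segment, point = p)
  # points below are authored for the right side; mirror_path flips Y for
  # the left and renames segments.
  mirror_path <- function(path, side) {
    if (side == "r") return(path)
    lapply(path, function(a) {
      seg <- sub("_r$", "_l", a$segment)
      list(segment = seg, point = a$point * c(1, -1, 1))
    })
  }

  for (side in c("r", "l")) {
    glut <- hip_attachment_sites(variant, subject, side)
    for (i in seq_len(nrow(glut))) {
      row <- strengths[strengths$group == glut$group[i], ]
      out[[length(out) + 1]] <- tibble::tibble(
        element = glut$element[i], group = glut$group[i], side = side,
        max_strength = row$strength_per_kg * M / row$n_elements,
        path = list(list(pt("pelvis", glut$origin[[i]]),
                         pt(paste0("thigh_", side), glut$insertion[[i]])))
      )
    }
    asis <-c(1.05 * d$blade_radius * cos(pi / 2 - d$flare) * d$ap,
              -(hb / 2 + 1.05 * d$blade_radius * sin(pi / 2 - d$flare)),
              d$blade_height)
    for (i in 1:3) {
      # straight-line proxy of the wrapped tendon: the effective line
      # of action passes anterior to the hip centre (flexion, slight
      # internal rotation)
      add("iliopsoas", side, i, mirror_path(list(
        pt("pelvis", c(0.16 * hb * d$ap, -0.12 * hb,
                       0.12 * hb + 0.03 * hb * (i - 2))),
        pt("pelvis", c(0.20 * hb, -0.45 * hb / 2 - 0.02, -0.02)),
        pt("thigh_r", c(0.006, 0.015, -0.05))), side))
    }
    # anterior pair (longus/brevis-like: anteromedial insertion, small
    # internal-rotation arm) and posterior pair (magnus-like)
    for (i in 1:4) {
      add("adductors", side, i, mirror_path(list(
        pt("pelvis", c(0.12 * hb * d$ap, -0.10 * hb - 0.01 * (i - 1),
                       -0.25 * hb)),
        pt("thigh_r", c(if (i <= 2) 0.015 else -0.01, 0.015,
                        -(0.35 + 0.13 * (i - 1)) * fl))), side))
    }
    for (i in 1:3) {
      add("hamstrings", side, i, mirror_path(list(
        pt("pelvis", c(-0.12 * hb * d$ap, -0.33 * hb, -0.35 * hb)),
        pt("shank_r", c(-0.03, 0.012 * (i - 2), -0.08 * sl))), side))
    }
    add("rectus_femoris", side, 1, mirror_path(list(
      pt("pelvis", asis + c(0, 0.01, -0.3 * d$blade_height)),
      pt("thigh_r", c(0.05, 0, -0.98 * fl)),
      pt("shank_r", c(0.045, 0, -0.08 * sl))), side))
    for (i in 1:3) {
      add("vasti", side, i, mirror_path(list(
        pt("thigh_r", c(0.02, 0.012 * (i - 2), -0.35 * fl)),
        pt("thigh_r", c(0.05, 0.008 * (i - 2), -0.98 * fl)),
        pt("shank_r", c(0.045, 0, -0.08 * sl))), side))
    }
    for (i in 1:2) {
      add("gastrocnemius", side, i, mirror_path(list(
        pt("thigh_r", c(-0.03, 0.015 * (2 * i - 3), -0.96 * fl)),
        pt("foot_r", c(-0.06, 0, -0.035))), side))
    }
    for (i in 1:2) {
      add("soleus", side, i, mirror_path(list(
        pt("shank_r", c(-0.025, 0.008 * (2 * i - 3), -0.3 * sl)),
        pt("foot_r", c(-0.06, 0, -0.035))), side))
    }
    for (i in 1:2) {
      add("tibialis_anterior", side, i, mirror_path(list(
        pt("shank_r", c(0.03, 0.008 * (2 * i - 3), -0.35 * sl)),
        pt("shank_r", c(0.045, 0, -0.95 * sl)),
        pt("foot_r", c(0.03, 0.01 * (2 * i - 3), -0.025))), side))
    }
    for (i in 1:2) {
      add("deep_rotators", side, i, mirror_path(list(
        pt("pelvis", c(-0.35 * hb * d$ap, -0.12 * hb, -0.02 - 0.02 * (i - 1))),
        pt("thigh_r", c(-0.025, -0.8 * nl, -0.01))), side))
    }
    # pectineus-like anterior adductor: pubic origin (independent of
    # iliac-blade flare), anteromedial proximal femur insertion --
    # flexes, adducts and internally rotates
    for (i in 1:2) {
      add("pectineus", side, i, mirror_path(list(
        pt("pelvis", c(0.16 * hb * d$ap, -0.07 * hb - 0.01 * i, -0.10 * hb)),
        pt("thigh_r", c(0.015, 0.022, -(0.10 + 0.03 * i)))), side))
    }
    add("tensor_fasciae_latae", side, 1, mirror_path(list(
      pt("pelvis", asis + c(0.005, -0.01, -0.01)),
      pt("thigh_r", c(0.01, -0.045, -0.3 * fl)),
      pt("shank_r", c(0.01, -0.03, -0.12 * sl))), side))
  }
  dplyr::bind_rows(out)
}

build_marker_set <- function(subject, d, fl, sl, foot_len, hat_len) {
  st <- subject$stature
  sc <- st / 1.7
  hb <- d$hb
  asis_y <- hb / 2 + 1.05 * d$blade_radius * sin(pi / 2 - d$flare)
  asis <- c(1.05 * d$blade_radius * cos(pi / 2 - d$flare) * d$ap, asis_y,
            d$blade_height)
  psis <- c(-0.55 * hb * d$ap, 0.16 * hb, d$blade_height * 0.95)
  rows <- list(
    list("LASI", "pelvis", asis), list("RASI", "pelvis", asis * c(1, -1, 1)),
    list("LPSI", "pelvis", psis), list("RPSI", "pelvis", psis * c(1, -1, 1))
  )
  hat <- list(
    FHD = c(0.06, 0.05, 0.98 * hat_len), BHD = c(-0.06, 0.05, 0.97 * hat_len),
    SHO = c(0, 0.20 * sc, 0.80 * hat_len), UPA = c(0.005, 0.24 * sc, 0.55 * hat_len),
    ELB = c(0.01, 0.25 * sc, 0.40 * hat_len), FRM = c(0.02, 0.26 * sc, 0.30 * hat_len),
    WRA = c(0.03, 0.285 * sc, 0.18 * hat_len), WRB = c(0.03, 0.255 * sc, 0.18 * hat_len),
    FIN = c(0.04, 0.27 * sc, 0.10 * hat_len), BAK = c(-0.07, 0.10 * sc, 0.70 * hat_len)
  )
  for (nm in names(hat)) {
    rows <- c(rows, list(list(paste0("L", nm), "hat", hat[[nm]]),
                         list(paste0("R", nm), "hat", hat[[nm]] * c(1, -1, 1))))
  }
  rows <- c(rows, list(
    list("CLAV", "hat", c(0.06, 0, 0.78 * hat_len)),
    list("STRN", "hat", c(0.08, 0, 0.60 * hat_len)),
    list("C7", "hat", c(-0.06, 0, 0.80 * hat_len)),
    list("T10", "hat", c(-0.08, 0, 0.55 * hat_len))
  ))
  leg <- function(side) {
    m <- if (side == "l") 1 else -1  # lateral Y sign
    th <- paste0("thigh_", side); sh <- paste0("shank_", side)
    ft <- paste0("foot_", side); P <- toupper(side)
    list(
      list(paste0(P, "THAP"), th, c(0.03, m * 0.06 * sc, -0.25 * fl)),
      list(paste0(P, "THAD"), th, c(0.04, m * 0.05 * sc, -0.60 * fl)),
      list(paste0(P, "THL"), th, c(0, m * 0.07 * sc, -0.45 * fl)),
      list(paste0(P, "KNEL"), th, c(0, m * 0.05 * sc, -0.97 * fl)),
      list(paste0(P, "KNEM"), th, c(0, -m * 0.05 * sc, -0.97 * fl)),
      list(paste0(P, "TIBP"), sh, c(0.03, m * 0.045 * sc, -0.30 * sl)),
      list(paste0(P, "TIBD"), sh, c(0.035, m * 0.04 * sc, -0.70 * sl)),
      list(paste0(P, "ANKL"), sh, c(0, m * 0.04 * sc, -0.96 * sl)),
      list(paste0(P, "ANKM"), sh, c(0, -m * 0.04 * sc, -0.96 * sl)),
      list(paste0(P, "HEE"), ft, c(-0.06 * sc, 0, -0.02)),
      list(paste0(P, "TOE"), ft, c(foot_len - 0.07 * sc, 0, -0.03)),
      list(paste0(P, "MT5"), ft, c(0.55 * foot_len, m * 0.04 * sc, -0.03))
    )
  }
  rows <- c(rows, leg("r"), leg("l"))
  tibble::tibble(
    marker = vapply(rows, `[[`, character(1), 1),
    segment = vapply(rows, `[[`, character(1), 2),
    point = lapply(rows, `[[`, 3)
  )
}

#' Neutral (upright standing) posture for a model
#' @param model a `skeleton_model`.
#' @param pelvis_height pelvis origin height (m); defaults to leg length.
#' @return named numeric vector over the model's coordinates.
#' @export
neutral_posture <- function(model, pelvis_height = NULL) {
  q <- stats::setNames(numeric(length(model$coord_names)), model$coord_names)
  q["pelvis_z"] <- pelvis_height %||%
    (model$subject$femur_length + model$dims$shank_length +
       model$dims$talus_height + 0.05)
  q
}

# Rodrigues rotation about unit axis.
rot_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Forward kinematics of a posture
#'
#' Poses the segment chain. With velocities/accelerations supplied, angular
#' velocity, angular acceleration and centre-of-mass acceleration are
#' propagated analytically through the chain (standard recursive rigid-body
#' kinematics), which is what the inverse-dynamics pass consumes.
#'
#' @param model a `skeleton_model`.
#' @param q named coordinate vector (see `model$coord_names`).
#' @param qd,qdd optional named velocity/acceleration vectors.
#' @return named list per segment: `R`, `origin`, `com`, and (if `qd`
#'   given) `omega`, `alpha`, `a_origin`, `a_com`; plus attribute
#'   `"axes"`: world direction of each rotational coordinate's axis.
#' @export
fk_state <- function(model, q, qd = NULL, qdd = NULL) {
  has_vel <- !is.null(qd)
  if (has_vel && is.null(qdd)) qdd <- qd * 0
  states <- list()
  axes <- list()
  for (nm in model$order) {
    sg <- model$segments[[nm]]
    if (is.na(sg$parent)) {
      R <- diag(3)
      p <- c(q[["pelvis_x"]], q[["pelvis_y"]], q[["pelvis_z"]])
      if (has_vel) {
        v <- c(qd[["pelvis_x"]], qd[["pelvis_y"]], qd[["pelvis_z"]])
        a <- c(qdd[["pelvis_x"]], qdd[["pelvis_y"]], qdd[["pelvis_z"]])
        om <- numeric(3); al <- numeric(3)
      }
    } else {
      par <- states[[sg$parent]]
      R <- par$R
      l_w <- par$R %*% sg$joint_location
      p <- par$origin + drop(l_w)
      if (has_vel) {
        om <- par$omega; al <- par$alpha
        a <- par$a_origin + cross3(par$alpha, l_w) +
          cross3(par$omega, cross3(par$omega, l_w))
      }
    }
    for (rot in sg$rotations) {
      aw <- drop(R %*% rot$axis)
      axes[[rot$coord]] <- aw
      if (has_vel) {
        al <- al + qdd[[rot$coord]] * aw + qd[[rot$coord]] * cross3(om, aw)
        om <- om + qd[[rot$coord]] * aw
      }
      R <- R %*% rot_axis(rot$axis, q[[rot$coord]])
    }
    st <- list(R = R, origin = drop(p), com = drop(p + R %*% sg$com))
    if (has_vel) {
      rc <- drop(R %*% sg$com)
      st$omega <- drop(om); st$alpha <- drop(al); st$a_origin <- drop(a)
      st$a_com <- drop(a) + drop(cross3(al, rc)) +
        drop(cross3(om, cross3(om, rc)))
    }
    states[[nm]] <- st
  }
  attr(states, "axes") <- axes
  states
}

cross3 <- function(a, b) {
  a <- drop(a); b <- drop(b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# World positions of all model markers at a posture: matrix with rownames.
marker_positions <- function(model, q, st = NULL) {
  if (is.null(st)) st <- fk_state(model, q)
  out <- matrix(0, nrow(model$markers), 3,
                dimnames = list(model$markers$marker, c("x", "y", "z")))
  pts <- do.call(rbind, model$markers$point)
  for (sg in unique(model$markers$segment)) {
    idx <- model$markers$segment == sg
    s <- st[[sg]]
    out[idx, ] <- sweep(pts[idx, , drop = FALSE] %*% t(s$R), 2, s$origin, "+")
  }
  out
}
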