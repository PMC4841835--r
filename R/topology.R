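#' Joint topology
#'
#' A topology names the tracked joints of a virtual skeleton and their
#' parent-child structure (a single rooted tree).  Built-in presets cover the
#' two common depth-camera layouts: 20 joints ("K1", Kinect v1) and 25 joints
#' ("K2", Kinect v2).  User-defined topologies are supported for other
#' capture hardware.
#'
#' @param name Identifier for the topology.
#' @param joint_names Character vector of unique joint identifiers, in
#'   canonical column order.
#' @param parent_of Named character vector mapping each non-root joint to its
#'   parent joint; the root joint is omitted.
#' @return An object of class `joint_topology`.
#' @export
#' @examples
#' topo <- joint_topology("chain", c("A", "B", "C"), c(B = "A", C = "B"))
#' topo$root
joint_topology <- function(name, joint_names, parent_of = character()) {
  stopifnot(is.character(name), length(name) == 1L)
  joint_names <- as.character(joint_names)
  if (length(joint_names) < 1L) stop("topology needs at least one joint")
  if (anyDuplicated(joint_names)) stop("joint names must be unique")
  parent_of <- parent_of[!is.na(parent_of)]
  children <- names(parent_of)
  if (is.null(children) && length(parent_of) > 0L)
    stop("parent_of must be a named character vector (child -> parent)")
  if (!all(children %in% joint_names))
    stop("parent_of names unknown joints: ",
         paste(setdiff(children, joint_names), collapse = ", "))
  if (!all(parent_of %in% joint_names))
    stop("parent_of refers to unknown parent joints: ",
         paste(setdiff(parent_of, joint_names), collapse = ", "))
  roots <- setdiff(joint_names, children)
  if (length(roots) != 1L)
    stop("parent graph must be a single rooted tree; found ",
         length(roots), " roots")
  # acyclicity: walk each joint to the root, never exceeding tree height
  for (j in joint_names) {
    cur <- j
    steps <- 0L
    while (cur != roots) {
      cur <- unname(parent_of[[cur]])
      steps <- steps + 1L
      if (steps > length(joint_names))
        stop("parent graph contains a cycle involving joint ", j)
    }
  }
  structure(
    list(name = name, joint_names = joint_names,
         parent_of = parent_of, root = roots),
    class = "joint_topology"
  )
}

#' @export
print.joint_topology <- function(x, ...) {
  cat("<joint_topology>", x$name, "-", length(x$joint_names),
      "joints, root:", x$root, "\n")
  invisible(x)
}

#' Built-in skeleton topologies
#'
#' `topology_k1()` is the 20-joint layout of the Kinect v1 skeleton;
#' `topology_k2()` the 25-joint Kinect v2 layout.  `get_topology()` resolves
#' a preset by name ("K1"/"K2") or passes through a `joint_topology`.
#'
#' @return A `joint_topology`.
#' @export
topology_k1 <- function() {
  joints <- c("HipCenter", "Spine", "ShoulderCenter", "Head",
              "ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft",
              "ShoulderRight", "ElbowRight", "WristRight", "HandRight",
              "HipLeft", "KneeLeft", "AnkleLeft", "FootLeft",
              "HipRight", "KneeRight", "AnkleRight", "FootRight")
  parents <- c(
    Spine = "HipCenter", ShoulderCenter = "Spine", Head = "ShoulderCenter",
    ShoulderLeft = "ShoulderCenter", ElbowLeft = "ShoulderLeft",
    WristLeft = "ElbowLeft", HandLeft = "WristLeft",
    ShoulderRight = "ShoulderCenter", ElbowRight = "ShoulderRight",
    WristRight = "ElbowRight", HandRight = "WristRight",
    HipLeft = "HipCenter", KneeLeft = "HipLeft",
    AnkleLeft = "KneeLeft", FootLeft = "AnkleLeft",
    HipRight = "HipCenter", KneeRight = "HipRight",
    AnkleRight = "KneeRight", FootRight = "AnkleRight")
  joint_topology("K1", joints, parents)
}

#' @rdname topology_k1
#' @export
topology_k2 <- function() {
  joints <- c("SpineBase", "SpineMid", "SpineShoulder", "Neck", "Head",
              "ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft",
              "HandTipLeft", "ThumbLeft",
              "ShoulderRight", "ElbowRight", "WristRight", "HandRight",
              "HandTipRight", "ThumbRight",
              "HipLeft", "KneeLeft", "AnkleLeft", "FootLeft",
              "HipRight", "KneeRight", "AnkleRight", "FootRight")
  parents <- c(
    SpineMid = "SpineBase", SpineShoulder = "SpineMid",
    Neck = "SpineShoulder", Head = "Neck",
    ShoulderLeft = "SpineShoulder", ElbowLeft = "ShoulderLeft",
    WristLeft = "ElbowLeft", HandLeft = "WristLeft",
    HandTipLeft = "HandLeft", ThumbLeft = "HandLeft",
    ShoulderRight = "SpineShoulder", ElbowRight = "ShoulderRight",
    WristRight = "ElbowRight", HandRight = "WristRight",
    HandTipRight = "HandRight", ThumbRight = "HandRight",
    HipLeft = "SpineBase", KneeLeft = "HipLeft",
    AnkleLeft = "KneeLeft", FootLeft = "AnkleLeft",
    HipRight = "SpineBase", KneeRight = "HipRight",
    AnkleRight = "KneeRight", FootRight = "AnkleRight")
  joint_topology("K2", joints, parents)
}

#' @rdname topology_k1
#' @param topology A `joint_topology`, or a preset name ("K1" or "K2").
#' @export
get_topology <- function(topology) {
  if (inherits(topology, "joint_topology")) return(topology)
  if (is.character(topology) && length(topology) == 1L) {
    return(switch(toupper(topology),
                  K1 = topology_k1(),
                  K2 = topology_k2(),
                  stop("unknown topology preset: ", topology)))
  }
  stop("topology must be a joint_topology or a preset name")
}
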