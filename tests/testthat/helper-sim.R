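# Shared simulation objects, built once per test run. The mesh/protocol
# pair and the trained reconstruction matrix are deterministic, so every
# test file can reuse them.

.fixtures <- new.env()

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) assign(name, build(), envir = .fixtures)
  .fixtures[[name]]
}

test_mesh <- function() fixture("mesh", function() build_mesh(1024L))

test_protocol <- function() fixture("protocol", function() adjacent_protocol())

test_sim <- function() fixture("sim", function() eit_simulator())

# forward solve for an ad-hoc phantom on the shared simulator mesh
sim_frame <- function(phantom, sim = test_sim()) {
  solve_forward(sim$mesh, element_conductivities(sim$mesh, phantom),
                sim$protocol, sim$struct)
}

# a single-inclusion phantom (bypasses the two-lungs-one-heart
# constraint; used for reconstruction point-target checks)
disk_phantom <- function(center, radius, conductivity = 2, background = 1) {
  structure(list(background_conductivity = background,
                 inclusions = list(list(label = "heart",
                                        center = as.numeric(center),
                                        radius = radius,
                                        conductivity = conductivity))),
            class = "thorax_phantom")
}
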