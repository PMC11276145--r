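# shared fixtures and independent oracles, all built in code

unit_cube <- function() box_mesh(c(0, 0, 0), c(1, 1, 1))

small_phantom_spec <- function(side = "right", ...) {
  phantom_spec(semi_axes = c(6, 5, 3.6), neck_length = 3, neck_radius = 2.4,
               lateral_offset = 25, pitch = 0.35, side = side, ...)
}

# exact two-sided Mann-Whitney p by full enumeration of labelings
enum_mw_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  all_v <- c(x, y)
  r <- rank(all_v)
  u_of <- function(ix) sum(r[ix]) - nx * (nx + 1) / 2
  u_obs <- u_of(seq_len(nx))
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2L, u_of)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# brute-force BFS flood fill oracle over a logical 3D array
bfs_fill_oracle <- function(region, seeds, connectivity = 26L) {
  dims <- dim(region)
  nb <- expand.grid(a = -1:1, b = -1:1, c = -1:1)
  nb <- nb[!(nb$a == 0 & nb$b == 0 & nb$c == 0), ]
  if (connectivity == 6L)
    nb <- nb[abs(nb$a) + abs(nb$b) + abs(nb$c) == 1, ]
  reached <- array(FALSE, dims)
  queue <- list()
  for (i in seq_len(nrow(seeds))) {
    s <- seeds[i, ]
    if (region[s[1], s[2], s[3]] && !reached[s[1], s[2], s[3]]) {
      reached[s[1], s[2], s[3]] <- TRUE
      queue[[length(queue) + 1L]] <- s
    }
  }
  while (length(queue) > 0) {
    p <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (j in seq_len(nrow(nb))) {
      q <- p + as.integer(nb[j, ])
      if (any(q < 1L) || any(q > dims)) next
      if (region[q[1], q[2], q[3]] && !reached[q[1], q[2], q[3]]) {
        reached[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1L]] <- q
      }
    }
  }
  reached
}

# volume of the ellipsoid (a,b,c) above the plane z = z0 (scaled sphere cap)
ellipsoid_cap_volume <- function(a, b, c, z0) {
  h <- c - z0
  pi * a * b / c^2 * h^2 * (3 * c - h) / 3
}

random_rigid <- function() {
  ax <- stats::rnorm(3)
  axis_angle_transform(ax, stats::runif(1, 0, 180), stats::rnorm(3, 0, 20))
}
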