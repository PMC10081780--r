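#include <Rcpp.h>
using namespace Rcpp;

// Lattice walk kernels. All randomness comes from R's RNG (unif_rand), so
// set.seed() in R makes every simulation reproducible bit-for-bit.
//
// Step rules:
//   lazy5 (rule 0): stay / +x / -x / +y / -y each with probability 1/5.
//   move4 (rule 1): +x / -x / +y / -y each with probability 1/4.
// Reflection rules at the top/left/right walls:
//   reject_stay (rule 0): an off-domain move leaves the bead in place.
//   mirror      (rule 1): an off-domain move bounces back one node.
// The bottom row (j == 0) is absorbing: a move landing there binds the bead
// at that node and time; bound beads stop updating.

static inline void draw_move(int rule, int &di, int &dj) {
  double u = unif_rand();
  if (rule == 0) { // lazy5
    if (u < 0.2)      { di = 0;  dj = 0;  }
    else if (u < 0.4) { di = 1;  dj = 0;  }
    else if (u < 0.6) { di = -1; dj = 0;  }
    else if (u < 0.8) { di = 0;  dj = 1;  }
    else              { di = 0;  dj = -1; }
  } else {         // move4
    if (u < 0.25)      { di = 1;  dj = 0;  }
    else if (u < 0.5)  { di = -1; dj = 0;  }
    else if (u < 0.75) { di = 0;  dj = 1;  }
    else               { di = 0;  dj = -1; }
  }
}

// [[Rcpp::export]]
List walk_absorb_cpp(IntegerVector i0, IntegerVector j0,
                     int nx, int ny, int max_steps,
                     int step_rule, int refl_rule,
                     int trace_every) {
  const int n = i0.size();
  std::vector<int> ii(i0.begin(), i0.end());
  std::vector<int> jj(j0.begin(), j0.end());
  std::vector<bool> bound(n, false);
  IntegerVector bind_step(n, NA_INTEGER);
  IntegerVector bind_node(n, NA_INTEGER);

  // immediate absorption for beads initialised on the bottom row
  int n_bound = 0;
  for (int b = 0; b < n; ++b) {
    if (jj[b] == 0) {
      bound[b] = true; bind_step[b] = 0; bind_node[b] = ii[b]; ++n_bound;
    }
  }

  bool tracing = trace_every > 0;
  int n_frames = tracing ? max_steps / trace_every + 1 : 0;
  IntegerMatrix trace_i(tracing ? n_frames : 0, tracing ? n : 0);
  IntegerMatrix trace_j(tracing ? n_frames : 0, tracing ? n : 0);
  IntegerVector frame_step(tracing ? n_frames : 0);
  int frame = 0;
  if (tracing) {
    for (int b = 0; b < n; ++b) { trace_i(0, b) = ii[b]; trace_j(0, b) = jj[b]; }
    frame_step[0] = 0;
    frame = 1;
  }

  int t = 0;
  for (t = 1; t <= max_steps && n_bound < n; ++t) {
    for (int b = 0; b < n; ++b) {
      if (bound[b]) continue;
      int di, dj;
      draw_move(step_rule, di, dj);
      int i_new = ii[b] + di;
      int j_new = jj[b] + dj;
      // reflecting walls: left (i<0), right (i>nx), top (j>ny)
      if (i_new < 0 || i_new > nx || j_new > ny) {
        if (refl_rule == 0) {        // reject_stay
          i_new = ii[b]; j_new = jj[b];
        } else {                     // mirror
          if (i_new < 0)  i_new = -i_new;
          if (i_new > nx) i_new = 2 * nx - i_new;
          if (j_new > ny) j_new = 2 * ny - j_new;
        }
      }
      ii[b] = i_new; jj[b] = j_new;
      if (j_new == 0) {              // absorbed by the fiber
        bound[b] = true; bind_step[b] = t; bind_node[b] = i_new; ++n_bound;
      }
    }
    if (tracing && t % trace_every == 0 && frame < n_frames) {
      for (int b = 0; b < n; ++b) { trace_i(frame, b) = ii[b]; trace_j(frame, b) = jj[b]; }
      frame_step[frame] = t;
      ++frame;
    }
  }

  List out = List::create(
    _["bound"] = LogicalVector(bound.begin(), bound.end()),
    _["bind_step"] = bind_step,
    _["bind_node"] = bind_node,
    _["final_i"] = IntegerVector(ii.begin(), ii.end()),
    _["final_j"] = IntegerVector(jj.begin(), jj.end()),
    _["steps_run"] = t - 1);
  if (tracing) {
    out["trace_i"] = trace_i(Range(0, frame - 1), _);
    out["trace_j"] = trace_j(Range(0, frame - 1), _);
    out["frame_step"] = frame_step[Range(0, frame - 1)];
  }
  return out;
}

// Free-space walk (no walls, no absorption) returning per-axis positions at
// checkpoint step counts; used to validate the walk's effective diffusivity.
// [[Rcpp::export]]
List walk_free_cpp(int n_walkers, IntegerVector checkpoints, int step_rule) {
  const int n_chk = checkpoints.size();
  int n_steps = n_chk > 0 ? checkpoints[n_chk - 1] : 0;
  std::vector<int> x(n_walkers, 0), y(n_walkers, 0);
  IntegerMatrix xs(n_chk, n_walkers), ys(n_chk, n_walkers);
  int chk = 0;
  while (chk < n_chk && checkpoints[chk] == 0) ++chk; // rows stay at origin
  for (int t = 1; t <= n_steps; ++t) {
    for (int b = 0; b < n_walkers; ++b) {
      int di, dj;
      draw_move(step_rule, di, dj);
      x[b] += di; y[b] += dj;
    }
    while (chk < n_chk && checkpoints[chk] == t) {
      for (int b = 0; b < n_walkers; ++b) { xs(chk, b) = x[b]; ys(chk, b) = y[b]; }
      ++chk;
    }
  }
  return List::create(_["x"] = xs, _["y"] = ys);
}
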