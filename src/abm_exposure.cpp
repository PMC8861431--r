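#include <Rcpp.h>
using namespace Rcpp;

// Explicit conservative finite-volume exposure kernel for the lattice
// spheroid model. Extracellular drug diffuses through the intercellular
// space (fraction eps_e of each occupied site) with tissue diffusivity
// D_s; empty sites belong to a well-mixed medium compartment. Each cell
// exchanges with its site's extracellular pool via first-order
// k_in/k_out, the prodrug chain is metabolised intracellularly at
// per-line rates, extracellular compound degrades at k_loss, and the
// terminal metabolite's consumption is routed to a sink. All fluxes in
// one step use pre-step concentrations, so mass is conserved exactly
// (to rounding) at every step. Sites with >= `direct_faces` faces open
// to the medium exchange directly with it: an isolated cell has no
// intercellular space, which makes the single-cell configuration the
// exact monolayer-ODE limit.
//
// Arguments: cell_of_site (ns, 0-based cell index per occupied site);
// neigh (ns x 6 neighbour indices into the site list, -1 = medium face);
// cell_line (0-based line index per cell); per-compound kin/kout/kloss
// (min^-1) and Ds (um^2/min); kmet (ncmp x nlines, min^-1); C_med0 (uM);
// V_med (um^3); Ci0 (ncell x ncmp); auc0 (ncell).
// [[Rcpp::export]]
List abm_exposure_cpp(IntegerVector cell_of_site,
                      IntegerMatrix neigh,
                      IntegerVector cell_line,
                      NumericVector kin, NumericVector kout,
                      NumericVector kloss,
                      NumericMatrix kmet,
                      LogicalVector cytotoxic,
                      NumericVector Ds,
                      double dx, double eps_e, double cell_frac,
                      NumericVector C_med0,
                      double V_med,
                      bool constant_boundary,
                      double duration, double dt,
                      int direct_faces,
                      NumericMatrix Ci0,
                      NumericVector auc0)
{
  const int ns = neigh.nrow();
  const int ncell = cell_line.size();
  const int ncmp = kin.size();
  const int nsteps = (int) std::ceil(duration / dt);
  const double step = duration / nsteps;

  const double V_site = dx * dx * dx;
  const double V_ext = eps_e * V_site;      // extracellular volume per site
  const double V_cell = cell_frac * V_site; // cell biovolume for bookkeeping
  const double vr = cell_frac / eps_e;      // cell-to-extracellular ratio

  NumericMatrix Ce(ns, ncmp);
  NumericMatrix Ci(clone(Ci0));
  NumericVector auc(clone(auc0));
  NumericVector C_med(clone(C_med0));
  double sink_ext = 0.0, sink_term = 0.0;

  // flatten the neighbour table; direct sites are encoded as medium (-1)
  // faces for their neighbours
  std::vector<bool> direct(ns, false);
  for (int s = 0; s < ns; ++s) {
    int m = 0;
    for (int f = 0; f < 6; ++f) if (neigh(s, f) < 0) ++m;
    direct[s] = (m >= direct_faces);
  }
  std::vector<int> nb(6 * (size_t) ns);
  std::vector<int> nmed(ns, 0);
  for (int s = 0; s < ns; ++s) {
    int m = 0;
    for (int f = 0; f < 6; ++f) {
      int v = neigh(s, f);
      if (v >= 0 && direct[v]) v = -1;
      if (v < 0) ++m;
      nb[(size_t) s * 6 + f] = v;
    }
    nmed[s] = m;
    if (direct[s])
      for (int j = 0; j < ncmp; ++j) Ce(s, j) = C_med0[j];
  }

  std::vector<double> dCe((size_t) ns * ncmp);
  std::vector<double> dCi((size_t) ncell * ncmp);
  std::vector<double> met(ncmp), dmed(ncmp);
  std::vector<bool> cyto(ncmp);
  for (int j = 0; j < ncmp; ++j) cyto[j] = cytotoxic[j];

  for (int it = 0; it < nsteps; ++it) {
    std::fill(dmed.begin(), dmed.end(), 0.0);
    double d_sink_ext = 0.0, d_sink_term = 0.0;

    // extracellular field: diffusion + degradation (pre-step values)
    for (int j = 0; j < ncmp; ++j) {
      const double difc = Ds[j] / (dx * dx);
      const double kl = kloss[j];
      const double cm = C_med[j];
      const double *ce = &Ce(0, j);
      double *d = &dCe[(size_t) j * ns];
      double dm = 0.0, sx = 0.0;
      for (int s = 0; s < ns; ++s) {
        if (direct[s]) { d[s] = 0.0; continue; }
        const int *n6 = &nb[(size_t) s * 6];
        const double c0 = ce[s];
        double acc = -6.0 * c0;
        for (int f = 0; f < 6; ++f) {
          const int v = n6[f];
          acc += (v < 0) ? cm : ce[v];
        }
        d[s] = difc * acc - kl * c0;
        if (nmed[s] > 0) dm -= difc * nmed[s] * (cm - c0) * V_ext;
        sx += kl * c0 * V_ext;
      }
      dmed[j] += dm;
      d_sink_ext += sx + kl * cm * V_med;
    }

    // cells: exchange + chain metabolism (pre-step Ce and Ci)
    for (int s = 0; s < ns; ++s) {
      const int c = cell_of_site[s];
      const int ln = cell_line[c];
      const bool dir = direct[s];
      double auc_add = 0.0;
      for (int j = 0; j < ncmp; ++j) met[j] = kmet(j, ln) * Ci(c, j);
      for (int j = 0; j < ncmp; ++j) {
        const double ci = Ci(c, j);
        const double Ce_loc = dir ? C_med[j] : Ce(s, j);
        const double exch = kin[j] * Ce_loc - kout[j] * ci;
        const double prod = (j > 0) ? met[j - 1] : 0.0;
        dCi[(size_t) j * ncell + c] = exch + prod - met[j];
        if (dir) dmed[j] -= exch * V_cell;
        else dCe[(size_t) j * ns + s] -= vr * exch;
        if (cyto[j]) auc_add += ci;
      }
      auc[c] += step * auc_add;
      d_sink_term += V_cell * met[ncmp - 1];
    }

    // apply updates
    for (int j = 0; j < ncmp; ++j) {
      double *ce = &Ce(0, j);
      const double *d = &dCe[(size_t) j * ns];
      for (int s = 0; s < ns; ++s)
        if (!direct[s]) ce[s] += step * d[s];
      double *cij = &Ci(0, j);
      const double *di = &dCi[(size_t) j * ncell];
      for (int c = 0; c < ncell; ++c) cij[c] += step * di[c];
    }
    if (!constant_boundary)
      for (int j = 0; j < ncmp; ++j)
        C_med[j] += step * (dmed[j] / V_med - kloss[j] * C_med[j]);
    for (int s = 0; s < ns; ++s)
      if (direct[s]) for (int j = 0; j < ncmp; ++j) Ce(s, j) = C_med[j];
    sink_ext += step * d_sink_ext;
    sink_term += step * d_sink_term;
  }

  return List::create(_["Ce"] = Ce, _["Ci"] = Ci, _["auc"] = auc,
                      _["C_med"] = C_med,
                      _["sink_ext"] = sink_ext, _["sink_term"] = sink_term,
                      _["dt"] = step, _["nsteps"] = nsteps);
}
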