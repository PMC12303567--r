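#include <Rcpp.h>
using namespace Rcpp;

// Two-state forward-backward over one chromosome, vectorized across cells.
// e_rm / e_by are (cells x sites) scaled emission likelihoods, r the
// recombination fractions of the len-1 adjacent intervals.
//
// Two chain models share this kernel. The symmetric chain (freq_chain =
// false) switches state with probability r and starts at pi_rm. The
// pool-frequency-weighted chain (freq_chain = true) recombines with
// probability r and then draws the new allele from the pool frequency f of
// the target site, starting from f at the first site; its state marginals
// therefore match the panel allele frequencies.
static inline void transition(const bool freq_chain, const double ri,
                              const double fi, double &t_rr, double &t_br,
                              double &t_rb, double &t_bb) {
  if (freq_chain) {
    t_rr = (1.0 - ri) + ri * fi;  // RM -> RM
    t_br = ri * fi;               // BY -> RM
    t_rb = ri * (1.0 - fi);       // RM -> BY
    t_bb = (1.0 - ri) + ri * (1.0 - fi);
  } else {
    t_rr = 1.0 - ri;
    t_br = ri;
    t_rb = ri;
    t_bb = 1.0 - ri;
  }
}

// [[Rcpp::export(name = ".fb_core")]]
List fb_core(NumericMatrix e_rm, NumericMatrix e_by, NumericVector r,
             double pi_rm, NumericVector f, bool freq_chain,
             bool want_suff) {
  const int n = e_rm.nrow(), len = e_rm.ncol();
  NumericMatrix a_rm(n, len), a_by(n, len), b_rm(n, len), b_by(n, len);
  NumericVector ll(n);
  const double pi1 = freq_chain ? f[0] : pi_rm;

  for (int c = 0; c < n; ++c) {
    double vr = pi1 * e_rm(c, 0), vb = (1.0 - pi1) * e_by(c, 0);
    double sc = vr + vb;
    ll[c] += std::log(sc);
    a_rm(c, 0) = vr / sc;
    a_by(c, 0) = vb / sc;
  }
  for (int i = 1; i < len; ++i) {
    double t_rr, t_br, t_rb, t_bb;
    transition(freq_chain, r[i - 1], f[i], t_rr, t_br, t_rb, t_bb);
    for (int c = 0; c < n; ++c) {
      double pr = a_rm(c, i - 1) * t_rr + a_by(c, i - 1) * t_br;
      double pb = a_rm(c, i - 1) * t_rb + a_by(c, i - 1) * t_bb;
      double vr = pr * e_rm(c, i), vb = pb * e_by(c, i);
      double sc = vr + vb;
      ll[c] += std::log(sc);
      a_rm(c, i) = vr / sc;
      a_by(c, i) = vb / sc;
    }
  }

  for (int c = 0; c < n; ++c) {
    b_rm(c, len - 1) = 1.0;
    b_by(c, len - 1) = 1.0;
  }
  for (int i = len - 2; i >= 0; --i) {
    double t_rr, t_br, t_rb, t_bb;
    transition(freq_chain, r[i], f[i + 1], t_rr, t_br, t_rb, t_bb);
    for (int c = 0; c < n; ++c) {
      double tr = e_rm(c, i + 1) * b_rm(c, i + 1);
      double tb = e_by(c, i + 1) * b_by(c, i + 1);
      double vr = t_rr * tr + t_rb * tb;
      double vb = t_br * tr + t_bb * tb;
      double sc = vr + vb;
      b_rm(c, i) = vr / sc;
      b_by(c, i) = vb / sc;
    }
  }

  NumericMatrix gamma(n, len);
  for (int i = 0; i < len; ++i) {
    for (int c = 0; c < n; ++c) {
      double gr = a_rm(c, i) * b_rm(c, i);
      double gb = a_by(c, i) * b_by(c, i);
      gamma(c, i) = gr / (gr + gb);
    }
  }

  List out = List::create(_["gamma"] = gamma, _["loglik"] = ll);
  if (want_suff && len > 1) {
    // expected recombination vs copy events per interval, summed over
    // cells (for the symmetric chain a "recombination" is a state switch)
    NumericVector sw(len - 1), st(len - 1);
    for (int i = 0; i + 1 < len; ++i) {
      const double ri = r[i];
      const double fi = f[i + 1];
      double s_sw = 0.0, s_st = 0.0;
      for (int c = 0; c < n; ++c) {
        double tr = e_rm(c, i + 1) * b_rm(c, i + 1);
        double tb = e_by(c, i + 1) * b_by(c, i + 1);
        double rec, copy;
        if (freq_chain) {
          rec = ri * (fi * tr + (1.0 - fi) * tb) *
                (a_rm(c, i) + a_by(c, i));
          copy = (1.0 - ri) * (a_rm(c, i) * tr + a_by(c, i) * tb);
        } else {
          rec = ri * (a_rm(c, i) * tb + a_by(c, i) * tr);
          copy = (1.0 - ri) * (a_rm(c, i) * tr + a_by(c, i) * tb);
        }
        double ps = rec / (rec + copy);
        s_sw += ps;
        s_st += 1.0 - ps;
      }
      sw[i] = s_sw;
      st[i] = s_st;
    }
    out["switch"] = sw;
    out["stay"] = st;
  } else if (want_suff) {
    out["switch"] = NumericVector(0);
    out["stay"] = NumericVector(0);
  }
  return out;
}

// Forward pass only: per-cell log-likelihood of one chromosome.
// [[Rcpp::export(name = ".fb_forward_ll")]]
NumericVector fb_forward_ll(NumericMatrix e_rm, NumericMatrix e_by,
                            NumericVector r, double pi_rm, NumericVector f,
                            bool freq_chain) {
  const int n = e_rm.nrow(), len = e_rm.ncol();
  NumericVector ll(n);
  std::vector<double> ar(n), ab(n);
  const double pi1 = freq_chain ? f[0] : pi_rm;
  for (int c = 0; c < n; ++c) {
    double vr = pi1 * e_rm(c, 0), vb = (1.0 - pi1) * e_by(c, 0);
    double sc = vr + vb;
    ll[c] += std::log(sc);
    ar[c] = vr / sc;
    ab[c] = vb / sc;
  }
  for (int i = 1; i < len; ++i) {
    double t_rr, t_br, t_rb, t_bb;
    transition(freq_chain, r[i - 1], f[i], t_rr, t_br, t_rb, t_bb);
    for (int c = 0; c < n; ++c) {
      double pr = ar[c] * t_rr + ab[c] * t_br;
      double pb = ar[c] * t_rb + ab[c] * t_bb;
      double vr = pr * e_rm(c, i), vb = pb * e_by(c, i);
      double sc = vr + vb;
      ll[c] += std::log(sc);
      ar[c] = vr / sc;
      ab[c] = vb / sc;
    }
  }
  return ll;
}
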