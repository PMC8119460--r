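#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Felsenstein pruning over site patterns for one site class.
//
// edge:      E x 2 matrix (parent, child) of 1-based node ids in postorder
//            (every child edge appears before its parent's edge)
// P:         list of E transition matrices (61 x 61), rows = from-state
// tipStates: ntip x npat integer matrix of codon states, 0 = missing
// pi:        61 stationary frequencies used at the root
// nNode:     number of internal nodes
//
// Returns the per-pattern log-likelihood. Underflow is handled by per-node
// rescaling of conditional likelihoods with accumulated log factors.
// [[Rcpp::export]]
arma::rowvec prunePatterns(const arma::imat& edge, const List& P,
                           const arma::imat& tipStates, const arma::vec& pi,
                           const int nNode) {
  const int ntip = tipStates.n_rows;
  const int npat = tipStates.n_cols;
  const int E = edge.n_rows;
  const int total = ntip + nNode;
  std::vector<arma::mat> part(total + 1);
  std::vector<bool> init(total + 1, false);
  std::vector<bool> scaled(total + 1, false);
  arma::rowvec logscale(npat, arma::fill::zeros);

  for (int e = 0; e < E; ++e) {
    const int parent = edge(e, 0);
    const int child = edge(e, 1);
    const arma::mat Pe = as<arma::mat>(P[e]);
    arma::mat contrib(61, npat);
    if (child <= ntip) {
      for (int p = 0; p < npat; ++p) {
        const int s = tipStates(child - 1, p);
        if (s > 0) contrib.col(p) = Pe.col(s - 1);
        else contrib.col(p).fill(1.0);  // missing data: rows of P sum to 1
      }
    } else {
      arma::mat& cp = part[child];
      if (!scaled[child]) {
        arma::rowvec m = arma::max(cp, 0);
        m.transform([](double v) { return v > 0.0 ? v : 1.0; });
        cp.each_row() /= m;
        logscale += arma::log(m);
        scaled[child] = true;
      }
      contrib = Pe * cp;
    }
    if (!init[parent]) {
      part[parent] = contrib;
      init[parent] = true;
    } else {
      part[parent] %= contrib;
    }
  }

  const int root = edge(E - 1, 0);
  arma::rowvec sitelik = pi.t() * part[root];
  arma::rowvec out(npat);
  for (int p = 0; p < npat; ++p) {
    out(p) = (sitelik(p) > 0.0 ? std::log(sitelik(p))
                               : -std::numeric_limits<double>::infinity()) +
             logscale(p);
  }
  return out;
}

// Pruning with one edge excluded: returns the conditional likelihoods of the
// subtree below the excluded edge ("sub") and of the remainder of the tree at
// the excluded edge's parent ("rest", the tree being rooted there), so that a
// site likelihood under any transition matrix P on the excluded edge is
// sum_i pi_i * rest(i) * (P %*% sub)(i), scaled by exp(logRest + logSub).
// Used by the branch-site fast path: the four site classes share the two
// background regimes and differ only on the single foreground branch.
//
// excludeEdge: 1-based row of `edge`; its parent must be the traversal root.
// inSub: 1-based node flags, true for nodes in the excluded subtree.
// [[Rcpp::export]]
List prunePartsExclude(const arma::imat& edge, const List& P,
                       const arma::imat& tipStates, const int nNode,
                       const int excludeEdge, const LogicalVector& inSub) {
  const int ntip = tipStates.n_rows;
  const int npat = tipStates.n_cols;
  const int E = edge.n_rows;
  const int total = ntip + nNode;
  std::vector<arma::mat> part(total + 1);
  std::vector<bool> init(total + 1, false);
  std::vector<bool> scaled(total + 1, false);
  arma::rowvec logRest(npat, arma::fill::zeros);
  arma::rowvec logSub(npat, arma::fill::zeros);
  arma::mat sub;

  for (int e = 0; e < E; ++e) {
    const int parent = edge(e, 0);
    const int child = edge(e, 1);
    if (e == excludeEdge - 1) {
      if (child <= ntip) {
        sub.set_size(61, npat);
        for (int p = 0; p < npat; ++p) {
          const int s = tipStates(child - 1, p);
          sub.col(p).zeros();
          if (s > 0) sub(s - 1, p) = 1.0;
          else sub.col(p).fill(1.0);
        }
      } else {
        arma::mat& cp = part[child];
        arma::rowvec m = arma::max(cp, 0);
        m.transform([](double v) { return v > 0.0 ? v : 1.0; });
        cp.each_row() /= m;
        logSub += arma::log(m);
        sub = cp;
      }
      continue;  // do not fold into the parent
    }
    const arma::mat Pe = as<arma::mat>(P[e]);
    arma::mat contrib(61, npat);
    if (child <= ntip) {
      for (int p = 0; p < npat; ++p) {
        const int s = tipStates(child - 1, p);
        if (s > 0) contrib.col(p) = Pe.col(s - 1);
        else contrib.col(p).fill(1.0);
      }
    } else {
      arma::mat& cp = part[child];
      if (!scaled[child]) {
        arma::rowvec m = arma::max(cp, 0);
        m.transform([](double v) { return v > 0.0 ? v : 1.0; });
        cp.each_row() /= m;
        if (inSub[child - 1]) logSub += arma::log(m);
        else logRest += arma::log(m);
        scaled[child] = true;
      }
      contrib = Pe * cp;
    }
    if (!init[parent]) {
      part[parent] = contrib;
      init[parent] = true;
    } else {
      part[parent] %= contrib;
    }
  }

  const int root = edge(E - 1, 0);
  arma::mat rest = init[root] ? part[root] : arma::mat(61, npat, arma::fill::ones);
  return List::create(Named("rest") = rest, Named("sub") = sub,
                      Named("logRest") = logRest, Named("logSub") = logSub);
}

// Full per-class pattern log-likelihoods of the four branch-site classes in
// one call: builds the scaled Goldman-Yang generators for omega in
// {omega0, 1, omega2}, exponentiates per branch through the symmetrized
// eigendecomposition, runs the two shared background-regime pruning passes
// with the foreground edge excluded, and combines each class's foreground
// transition matrix at the root. Mirrors the R reference path exactly.
//
// pairType: 61x61 codon-pair classification (0 none, 1 syn tv, 2 syn ti,
//           3 nonsyn tv, 4 nonsyn ti); pi: stationary frequencies.
// [[Rcpp::export]]
arma::mat cllBranchSite(const arma::imat& pairType, const arma::vec& pi,
                        const double kappa, const double w0, const double w2,
                        const arma::imat& edge, const arma::vec& lengths,
                        const int fgIdx, const LogicalVector& inSub,
                        const arma::imat& tipStates, const int nNode,
                        const double fgLen) {
  const int ntip = tipStates.n_rows;
  const int npat = tipStates.n_cols;
  const int E = edge.n_rows;
  const arma::vec s = arma::sqrt(pi);

  // all class generators share the neutral (omega = 1) rate scale, so
  // branch lengths are neutral-site substitutions per codon and omega > 1
  // classes evolve proportionally faster
  double neutralRate = 0.0;
  for (int i = 0; i < 61; ++i)
    for (int j = 0; j < 61; ++j) {
      const int t = pairType(i, j);
      if (t == 0) continue;
      neutralRate += pi(i) * pi(j) * ((t == 2 || t == 4) ? kappa : 1.0);
    }

  // decompositions for the distinct omegas among {w0, 1, w2}
  std::vector<double> oms{w0, 1.0, w2};
  std::vector<int> omIdx(3);
  std::vector<arma::vec> evals;
  std::vector<arma::mat> rights, lefts;
  for (int k = 0; k < 3; ++k) {
    int found = -1;
    for (int j = 0; j < k; ++j)
      if (oms[j] == oms[k]) { found = omIdx[j]; break; }
    if (found >= 0) { omIdx[k] = found; continue; }
    const double w = oms[k];
    arma::mat Q(61, 61, arma::fill::zeros);
    for (int i = 0; i < 61; ++i) {
      double rowsum = 0.0;
      for (int j = 0; j < 61; ++j) {
        const int t = pairType(i, j);
        if (t == 0) continue;
        double fac = pi(j);
        if (t == 2 || t == 4) fac *= kappa;
        if (t >= 3) fac *= w;
        Q(i, j) = fac;
        rowsum += fac;
      }
      Q(i, i) = -rowsum;
    }
    if (neutralRate > 0) Q /= neutralRate;
    arma::mat B = Q;
    B.each_col() %= s;
    B.each_row() /= s.t();
    B = 0.5 * (B + B.t());
    arma::vec ev;
    arma::mat U;
    arma::eig_sym(ev, U, B);
    arma::mat right = U;
    right.each_col() /= s;
    arma::mat left = U.t();
    left.each_row() %= s.t();
    omIdx[k] = evals.size();
    evals.push_back(ev);
    rights.push_back(right);
    lefts.push_back(left);
  }
  auto Pof = [&](int di, double t) {
    arma::mat P = rights[di];
    P.each_row() %= arma::exp(evals[di].t() * t);
    P = P * lefts[di];
    P.transform([](double v) { return v < 0.0 ? 0.0 : v; });
    return P;
  };

  // one pruning pass per background regime, foreground edge excluded
  auto pass = [&](int di) {
    const int total = ntip + nNode;
    std::vector<arma::mat> part(total + 1);
    std::vector<bool> init(total + 1, false);
    arma::rowvec logRest(npat, arma::fill::zeros);
    arma::rowvec logSub(npat, arma::fill::zeros);
    arma::mat sub;
    for (int e = 0; e < E; ++e) {
      const int parent = edge(e, 0);
      const int child = edge(e, 1);
      if (e == fgIdx - 1) {
        if (child <= ntip) {
          sub.set_size(61, npat);
          for (int p = 0; p < npat; ++p) {
            const int st = tipStates(child - 1, p);
            if (st > 0) { sub.col(p).zeros(); sub(st - 1, p) = 1.0; }
            else sub.col(p).fill(1.0);
          }
        } else {
          arma::mat& cp = part[child];
          arma::rowvec m = arma::max(cp, 0);
          m.transform([](double v) { return v > 0.0 ? v : 1.0; });
          cp.each_row() /= m;
          logSub += arma::log(m);
          sub = cp;
        }
        continue;
      }
      const arma::mat Pe = Pof(di, lengths(e));
      arma::mat contrib(61, npat);
      if (child <= ntip) {
        for (int p = 0; p < npat; ++p) {
          const int st = tipStates(child - 1, p);
          if (st > 0) contrib.col(p) = Pe.col(st - 1);
          else contrib.col(p).fill(1.0);
        }
      } else {
        arma::mat& cp = part[child];
        arma::rowvec m = arma::max(cp, 0);
        m.transform([](double v) { return v > 0.0 ? v : 1.0; });
        cp.each_row() /= m;
        if (inSub[child - 1]) logSub += arma::log(m);
        else logRest += arma::log(m);
        contrib = Pe * cp;
      }
      if (!init[parent]) { part[parent] = contrib; init[parent] = true; }
      else part[parent] %= contrib;
    }
    const int root = edge(E - 1, 0);
    arma::mat rest = init[root] ? part[root]
                                : arma::mat(61, npat, arma::fill::ones);
    arma::rowvec logscale = logRest + logSub;
    return std::make_tuple(rest, sub, logscale);
  };
  auto regA = pass(omIdx[0]);   // conserved background (omega0)
  auto regB = pass(omIdx[1]);   // neutral background (omega = 1)

  arma::mat P0 = Pof(omIdx[0], fgLen);
  arma::mat P1 = Pof(omIdx[1], fgLen);
  arma::mat P2 = Pof(omIdx[2], fgLen);

  auto comb = [&](const std::tuple<arma::mat, arma::mat, arma::rowvec>& reg,
                  const arma::mat& P) {
    const arma::mat v = std::get<0>(reg) % (P * std::get<1>(reg));
    arma::rowvec lik = pi.t() * v;
    arma::rowvec out(npat);
    for (int p = 0; p < npat; ++p)
      out(p) = (lik(p) > 0.0 ? std::log(lik(p))
                             : -std::numeric_limits<double>::infinity()) +
               std::get<2>(reg)(p);
    return out;
  };
  arma::mat cll(4, npat);
  cll.row(0) = comb(regA, P0);
  cll.row(1) = comb(regB, P1);
  cll.row(2) = comb(regA, P2);
  cll.row(3) = comb(regB, P2);
  return cll;
}

// Generic per-class pattern log-likelihoods: one pruning pass per site
// class, with per-edge omegas supplied as a matrix (classes x edges).
// Generators share the neutral-rate scale (see cllBranchSite). Transition
// matrices are cached per distinct (omega, edge) pair.
// [[Rcpp::export]]
arma::mat cllClasses(const arma::imat& pairType, const arma::vec& pi,
                     const double kappa, const arma::mat& omegaByEdge,
                     const arma::imat& edge, const arma::vec& lengths,
                     const arma::imat& tipStates, const int nNode) {
  const int ntip = tipStates.n_rows;
  const int npat = tipStates.n_cols;
  const int E = edge.n_rows;
  const int nclass = omegaByEdge.n_rows;
  const arma::vec s = arma::sqrt(pi);

  double neutralRate = 0.0;
  for (int i = 0; i < 61; ++i)
    for (int j = 0; j < 61; ++j) {
      const int t = pairType(i, j);
      if (t == 0) continue;
      neutralRate += pi(i) * pi(j) * ((t == 2 || t == 4) ? kappa : 1.0);
    }

  // distinct omegas
  std::vector<double> oms;
  arma::imat omIdx(nclass, E);
  for (int c = 0; c < nclass; ++c)
    for (int e = 0; e < E; ++e) {
      const double w = omegaByEdge(c, e);
      int found = -1;
      for (size_t j = 0; j < oms.size(); ++j)
        if (oms[j] == w) { found = j; break; }
      if (found < 0) { found = oms.size(); oms.push_back(w); }
      omIdx(c, e) = found;
    }
  std::vector<arma::vec> evals(oms.size());
  std::vector<arma::mat> rights(oms.size()), lefts(oms.size());
  for (size_t d = 0; d < oms.size(); ++d) {
    const double w = oms[d];
    arma::mat Q(61, 61, arma::fill::zeros);
    for (int i = 0; i < 61; ++i) {
      double rowsum = 0.0;
      for (int j = 0; j < 61; ++j) {
        const int t = pairType(i, j);
        if (t == 0) continue;
        double fac = pi(j);
        if (t == 2 || t == 4) fac *= kappa;
        if (t >= 3) fac *= w;
        Q(i, j) = fac;
        rowsum += fac;
      }
      Q(i, i) = -rowsum;
    }
    if (neutralRate > 0) Q /= neutralRate;
    arma::mat B = Q;
    B.each_col() %= s;
    B.each_row() /= s.t();
    B = 0.5 * (B + B.t());
    arma::eig_sym(evals[d], rights[d], B);
    lefts[d] = rights[d].t();
    lefts[d].each_row() %= s.t();
    rights[d].each_col() /= s;
  }
  // P cache per (distinct omega, edge)
  std::vector<std::vector<arma::mat>> Pcache(oms.size(),
                                             std::vector<arma::mat>(E));
  std::vector<std::vector<bool>> haveP(oms.size(),
                                       std::vector<bool>(E, false));
  auto Pof = [&](int d, int e) -> const arma::mat& {
    if (!haveP[d][e]) {
      arma::mat P = rights[d];
      P.each_row() %= arma::exp(evals[d].t() * lengths(e));
      P = P * lefts[d];
      P.transform([](double v) { return v < 0.0 ? 0.0 : v; });
      Pcache[d][e] = P;
      haveP[d][e] = true;
    }
    return Pcache[d][e];
  };

  arma::mat cll(nclass, npat);
  const int total = ntip + nNode;
  for (int c = 0; c < nclass; ++c) {
    std::vector<arma::mat> part(total + 1);
    std::vector<bool> init(total + 1, false);
    arma::rowvec logscale(npat, arma::fill::zeros);
    for (int e = 0; e < E; ++e) {
      const int parent = edge(e, 0);
      const int child = edge(e, 1);
      const arma::mat& Pe = Pof(omIdx(c, e), e);
      arma::mat contrib(61, npat);
      if (child <= ntip) {
        for (int p = 0; p < npat; ++p) {
          const int st = tipStates(child - 1, p);
          if (st > 0) contrib.col(p) = Pe.col(st - 1);
          else contrib.col(p).fill(1.0);
        }
      } else {
        arma::mat& cp = part[child];
        arma::rowvec m = arma::max(cp, 0);
        m.transform([](double v) { return v > 0.0 ? v : 1.0; });
        cp.each_row() /= m;
        logscale += arma::log(m);
        contrib = Pe * cp;
      }
      if (!init[parent]) { part[parent] = contrib; init[parent] = true; }
      else part[parent] %= contrib;
    }
    const int root = edge(E - 1, 0);
    arma::rowvec lik = pi.t() * part[root];
    for (int p = 0; p < npat; ++p)
      cll(c, p) = (lik(p) > 0.0 ? std::log(lik(p))
                                : -std::numeric_limits<double>::infinity()) +
                  logscale(p);
  }
  return cll;
}

// Profile the mixture log-likelihood over class proportions for fixed
// per-class pattern log-likelihoods: EM warmup with closed-form M-step,
// then damped Newton with an adaptive Levenberg ridge (mirrors the R
// reference in .profileMixtureRef). "branchsite" ties the four class
// proportions to (q, r); "simplex" frees the weights.
static double mixValue(const arma::vec& props, const arma::mat& M,
                       const arma::vec& w, const double baseSum) {
  arma::rowvec D = props.t() * M;
  if (D.min() <= 0.0) return -std::numeric_limits<double>::infinity();
  return arma::dot(w, arma::log(D).t()) + baseSum;
}

// [[Rcpp::export]]
arma::vec profileBSMix(const arma::mat& cll, const arma::vec& w,
                       const double q0, const double r0) {
  const int npat = cll.n_cols;
  arma::rowvec base = arma::max(cll, 0);
  base.transform([](double v) { return std::isfinite(v) ? v : 0.0; });
  arma::mat M = arma::exp(cll.each_row() - base);
  const double baseSum = arma::dot(w, base.t());
  const double eps = 1e-7;
  auto clampQR = [&](double& q, double& r) {
    q = std::min(std::max(q, eps), 1 - eps);
    r = std::min(std::max(r, eps), 1 - eps);
  };
  auto propsOf = [](double q, double r) {
    return arma::vec{q * r, q * (1 - r), (1 - q) * r, (1 - q) * (1 - r)};
  };
  double q = q0, r = r0;
  clampQR(q, r);
  // EM warmup
  for (int it = 0; it < 30; ++it) {
    arma::vec props = propsOf(q, r);
    arma::rowvec D = props.t() * M;
    if (D.min() <= 0.0) return arma::vec{-arma::datum::inf, q, r};
    arma::vec Gam = props % (M * (w / D.t()));
    const double tot = arma::accu(Gam);
    q = (Gam(0) + Gam(1)) / tot;
    r = (Gam(0) + Gam(2)) / tot;
    clampQR(q, r);
  }
  double ll = mixValue(propsOf(q, r), M, w, baseSum);
  double lam = 1e-8;
  int stall = 0;
  for (int it = 0; it < 200; ++it) {
    arma::vec props = propsOf(q, r);
    arma::rowvec D = props.t() * M;
    arma::vec g = M * (w / D.t());
    arma::mat U = M;
    U.each_row() %= (arma::sqrt(w).t() / D);
    arma::mat Hpp = -(U * U.t());
    arma::vec Jq{r, 1 - r, -r, -(1 - r)};
    arma::vec Jr{q, -q, 1 - q, -(1 - q)};
    arma::vec sgn{1, -1, -1, 1};
    arma::vec grad{arma::dot(g, Jq), arma::dot(g, Jr)};
    const double cross = arma::dot(Jq.t() * Hpp, Jr) + arma::dot(g, sgn);
    arma::mat H(2, 2);
    H(0, 0) = arma::dot(Jq.t() * Hpp, Jq);
    H(0, 1) = H(1, 0) = cross;
    H(1, 1) = arma::dot(Jr.t() * Hpp, Jr);
    const double scale = std::max(std::max(std::abs(H(0, 0)),
                                           std::abs(H(1, 1))), 1.0);
    bool accepted = false;
    double improved = 0.0;
    for (int tries = 0; tries < 12; ++tries) {
      arma::mat Hd = H;
      Hd.diag() -= lam * scale;
      arma::vec step;
      const bool okSolve = arma::solve(step, Hd, grad,
                                       arma::solve_opts::no_approx);
      if (okSolve) {
        if (arma::dot(step, grad) > 0) step = -step;
        double qc = q - step(0), rc = r - step(1);
        clampQR(qc, rc);
        const double llC = mixValue(propsOf(qc, rc), M, w, baseSum);
        if (llC >= ll) {
          improved = llC - ll;
          q = qc; r = rc; ll = llC;
          lam = std::max(lam / 10, 1e-12);
          accepted = true;
          break;
        }
      }
      lam *= 10;
    }
    if (!accepted) break;
    if (improved < 1e-11) {
      if (++stall >= 2) break;
    } else stall = 0;
  }
  return arma::vec{ll, q, r};
}

// [[Rcpp::export]]
arma::vec profileSimplexMix(const arma::mat& cll, const arma::vec& w,
                            const arma::vec& start) {
  const int nc = cll.n_rows;
  arma::rowvec base = arma::max(cll, 0);
  base.transform([](double v) { return std::isfinite(v) ? v : 0.0; });
  arma::mat M = arma::exp(cll.each_row() - base);
  const double baseSum = arma::dot(w, base.t());
  const double eps = 1e-7;
  arma::vec par = start / arma::accu(start);
  par = arma::clamp(par, eps, 1.0);
  par /= arma::accu(par);
  arma::vec v = par.head(nc - 1);
  auto propsOf = [&](const arma::vec& vv) {
    arma::vec p(nc);
    p.head(nc - 1) = vv;
    p(nc - 1) = 1.0 - arma::accu(vv);
    return p;
  };
  auto project = [&](arma::vec vv) {
    vv = arma::clamp(vv, eps, 1.0);
    const double tot = arma::accu(vv);
    if (tot > 1.0 - eps) vv *= (1.0 - eps) / tot;
    return vv;
  };
  v = project(v);
  // EM warmup on the full simplex
  for (int it = 0; it < 30; ++it) {
    arma::vec props = propsOf(v);
    arma::rowvec D = props.t() * M;
    if (D.min() <= 0.0) return arma::join_cols(
        arma::vec{-arma::datum::inf}, propsOf(v));
    arma::vec Gam = props % (M * (w / D.t()));
    arma::vec p = Gam / arma::accu(Gam);
    p = arma::clamp(p, eps, 1.0);
    p /= arma::accu(p);
    v = project(p.head(nc - 1));
  }
  double ll = mixValue(propsOf(v), M, w, baseSum);
  double lam = 1e-8;
  int stall = 0;
  for (int it = 0; it < 200; ++it) {
    arma::vec props = propsOf(v);
    arma::rowvec D = props.t() * M;
    arma::vec g = M * (w / D.t());
    arma::mat U = M;
    U.each_row() %= (arma::sqrt(w).t() / D);
    arma::mat Hpp = -(U * U.t());
    arma::vec grad = g.head(nc - 1) - g(nc - 1);
    arma::mat H = Hpp.submat(0, 0, nc - 2, nc - 2);
    for (int i = 0; i < nc - 1; ++i)
      for (int j = 0; j < nc - 1; ++j)
        H(i, j) += Hpp(nc - 1, nc - 1) - Hpp(i, nc - 1) - Hpp(nc - 1, j);
    double scale = 1.0;
    for (int i = 0; i < nc - 1; ++i)
      scale = std::max(scale, std::abs(H(i, i)));
    bool accepted = false;
    double improved = 0.0;
    for (int tries = 0; tries < 12; ++tries) {
      arma::mat Hd = H;
      Hd.diag() -= lam * scale;
      arma::vec step;
      const bool okSolve = arma::solve(step, Hd, grad,
                                       arma::solve_opts::no_approx);
      if (okSolve) {
        if (arma::dot(step, grad) > 0) step = -step;
        arma::vec vc = project(v - step);
        const double llC = mixValue(propsOf(vc), M, w, baseSum);
        if (llC >= ll) {
          improved = llC - ll;
          v = vc; ll = llC;
          lam = std::max(lam / 10, 1e-12);
          accepted = true;
          break;
        }
      }
      lam *= 10;
    }
    if (!accepted) break;
    if (improved < 1e-11) {
      if (++stall >= 2) break;
    } else stall = 0;
  }
  arma::vec props = propsOf(v);
  props /= arma::accu(props);
  return arma::join_cols(arma::vec{ll}, props);
}
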