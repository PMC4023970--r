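// Metropolis-within-Gibbs samplers for the truncated-Poisson mixture
// models. The per-pair mixture weights are integrated out analytically
// (each pair's weight vector carries exactly one categorical
// observation, so P(z = k | eta) = alpha_k / sum(alpha) exactly); the
// chains below are collapsed Gibbs samplers of the same posterior. All
// randomness goes through the R RNG so that set.seed() in R makes every
// chain reproducible.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// log P(X >= T) for X ~ Pois(lam)
static inline double logUpper(double lam, int T) {
    if (T <= 0) return 0.0;
    return R::ppois(T - 1, lam, 0, 1);
}

// log P(X <= T-1)
static inline double logLower(double lam, int T) {
    return R::ppois(T - 1, lam, 1, 1);
}

// log normalizer of the joint-max truncation: log(1 - F(T-1;a)F(T-1;b))
static inline double logZjoint(double a, double b, int T) {
    return log1p(-std::exp(logLower(a, T) + logLower(b, T)));
}

static inline double clampProb(double p) {
    if (p < 1e-300) return 1e-300;
    if (p > 1.0 - 1e-16) return 1.0 - 1e-16;
    return p;
}

// categorical draw from unnormalized log weights
static inline int drawCat(const double *lw, int K) {
    double m = lw[0];
    for (int k = 1; k < K; ++k) if (lw[k] > m) m = lw[k];
    double w[8], s = 0.0;
    for (int k = 0; k < K; ++k) { w[k] = std::exp(lw[k] - m); s += w[k]; }
    double u = unif_rand() * s, c = 0.0;
    for (int k = 0; k < K; ++k) { c += w[k]; if (u <= c) return k; }
    return K - 1;
}

// reflected uniform proposal on (0, upper)
static inline double reflectProp(double cur, double hw, double upper) {
    double p = cur + (2.0 * unif_rand() - 1.0) * hw;
    for (int it = 0; it < 64; ++it) {
        if (p < 0.0) { p = -p; continue; }
        if (p > upper) { p = 2.0 * upper - p; continue; }
        break;
    }
    if (p <= 0.0 || p > upper) p = cur;
    return p;
}

// ---------------------------------------------------------------- onestep

static bool onestepOk(const double *l) {
    // order: l01 l02 l1 l21 l22 l3 l4 lF1 lF2
    for (int j = 0; j < 9; ++j)
        if (!(l[j] > 0.0) || !std::isfinite(l[j])) return false;
    double F1 = l[7], F2 = l[8];
    return l[0] > F1 && l[2] > F1 && l[3] > F1 && l[5] > F1 &&
           l[1] > F2 && l[2] > F2 && l[4] > F2 && l[6] > F2 &&
           l[0] > l[1] && l[3] < l[4];
}

static void onestepRates(const double *l, double *la, double *lb) {
    la[0] = l[0]; lb[0] = l[1];
    la[1] = l[2]; lb[1] = l[2];
    la[2] = l[3]; lb[2] = l[4];
    la[3] = l[5]; lb[3] = l[8];
    la[4] = l[7]; lb[4] = l[6];
    la[5] = l[7]; lb[5] = l[8];
}

// component loglik from sufficient stats (lgamma(x+1) terms dropped: they
// are constant in the parameters)
static inline double compLikStats(double S1, double S2, double n,
                                  double a, double b, double lz) {
    if (n == 0.0) return 0.0;
    return S1 * std::log(a) + S2 * std::log(b) - n * (a + b) - n * lz;
}

// [[Rcpp::export]]
List cpp_run_onestep(IntegerMatrix X, int T, NumericMatrix base,
                     double alpha5, bool covariate,
                     NumericVector lamInit, double aT0, double bT0,
                     double aF0, double bF0, double eta0,
                     int nIter, int burnIn, int thin,
                     double propSd, double etaHw, double C, double E) {
    const int n = X.nrow(), K = 6;
    double lam[9];
    for (int j = 0; j < 9; ++j) lam[j] = lamInit[j];
    if (!onestepOk(lam)) stop("initial intensities violate the constraints");
    double aT = aT0, bT = bT0, aF = aF0, bF = bF0, eta = eta0;

    double la[6], lb[6], lz[6];
    onestepRates(lam, la, lb);
    for (int k = 0; k < K; ++k) lz[k] = logZjoint(la[k], lb[k], T);

    // collapsed weight prior: alpha_ik = eta * base_ik (k < 5), alpha5
    std::vector<double> logb(static_cast<size_t>(n) * 5), Bi(n);
    const double logA5 = std::log(alpha5);
    for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int k = 0; k < 5; ++k) {
            double b = base(i, k);
            logb[static_cast<size_t>(i) * 5 + k] = std::log(b);
            s += b;
        }
        Bi[i] = s;
    }

    std::vector<int> z(n, 5);
    std::vector<double> sharedLogpi(K, std::log(1.0 / K));

    IntegerMatrix zcount(n, K);
    const int nDraw = (nIter > burnIn) ? (nIter - burnIn + thin - 1) / thin : 0;
    NumericMatrix draws(nDraw, 14);
    int drawRow = 0;
    const int nPar = 14; // 9 lams, aT,bT,aF,bF, eta
    std::vector<double> accept(nPar, 0.0), attempt(nPar, 0.0);

    double nk[6], S1[6], S2[6];

    for (int iter = 0; iter < nIter; ++iter) {
        // --- z sweep (collapsed weights) and sufficient stats
        double c1[6], c2[6], c0[6];
        for (int k = 0; k < K; ++k) {
            c1[k] = std::log(la[k]);
            c2[k] = std::log(lb[k]);
            c0[k] = -(la[k] + lb[k]) - lz[k];
        }
        const double logEta = std::log(eta);
        for (int k = 0; k < K; ++k) { nk[k] = 0; S1[k] = 0; S2[k] = 0; }
        double nScaled = 0.0; // pairs currently in an eta-scaled category
        for (int i = 0; i < n; ++i) {
            double lw[6];
            double x1 = X(i, 0), x2 = X(i, 1);
            if (covariate) {
                const double *lbi = &logb[static_cast<size_t>(i) * 5];
                for (int k = 0; k < 5; ++k)
                    lw[k] = logEta + lbi[k] +
                            x1 * c1[k] + x2 * c2[k] + c0[k];
                lw[5] = logA5 + x1 * c1[5] + x2 * c2[5] + c0[5];
            } else {
                for (int k = 0; k < K; ++k)
                    lw[k] = sharedLogpi[k] +
                            x1 * c1[k] + x2 * c2[k] + c0[k];
            }
            int zi = drawCat(lw, K);
            z[i] = zi;
            nk[zi] += 1.0; S1[zi] += x1; S2[zi] += x2;
            if (zi < 5) nScaled += 1.0;
            if (iter >= burnIn) zcount(i, zi)++;
        }

        if (!covariate) {
            // shared weight vector, flat Dirichlet prior (ablation mode)
            double g[6], s = 0.0;
            for (int k = 0; k < K; ++k) {
                g[k] = R::rgamma(1.0 + nk[k], 1.0) + 1e-300;
                s += g[k];
            }
            for (int k = 0; k < K; ++k)
                sharedLogpi[k] = std::log(clampProb(g[k] / s));
        }

        // --- intensity MH (log-normal random walk)
        static const int compOf[9][2] = {
            {0, -1}, {0, -1}, {1, -1}, {2, -1}, {2, -1},
            {3, -1}, {4, -1}, {4, 5}, {3, 5}};
        for (int j = 0; j < 9; ++j) {
            attempt[j] += 1.0;
            double cur = lam[j];
            double prop = cur * std::exp(propSd * norm_rand());
            double lamNew[9];
            for (int q = 0; q < 9; ++q) lamNew[q] = lam[q];
            lamNew[j] = prop;
            if (!onestepOk(lamNew)) continue;
            double laN[6], lbN[6];
            onestepRates(lamNew, laN, lbN);
            double dlik = 0.0;
            for (int c = 0; c < 2; ++c) {
                int k = compOf[j][c];
                if (k < 0) break;
                double lzN = logZjoint(laN[k], lbN[k], T);
                dlik += compLikStats(S1[k], S2[k], nk[k], laN[k], lbN[k], lzN)
                      - compLikStats(S1[k], S2[k], nk[k], la[k], lb[k], lz[k]);
            }
            double dpri;
            if (j <= 6)
                dpri = R::dgamma(prop, aT, 1.0 / bT, 1) -
                       R::dgamma(cur,  aT, 1.0 / bT, 1);
            else
                dpri = R::dgamma(prop, aF, 1.0 / bF, 1) -
                       R::dgamma(cur,  aF, 1.0 / bF, 1);
            double lacc = dlik + dpri + std::log(prop / cur);
            if (std::log(unif_rand()) < lacc) {
                lam[j] = prop;
                onestepRates(lam, la, lb);
                for (int c = 0; c < 2; ++c) {
                    int k = compOf[j][c];
                    if (k < 0) break;
                    lz[k] = logZjoint(la[k], lb[k], T);
                }
                accept[j] += 1.0;
            }
        }

        // --- hyperparameter MH (uniform(0, C] priors, log-normal RW)
        auto gammaSetLik = [&](double sh, double rt, int lo, int hi) {
            double s = 0.0;
            for (int j = lo; j <= hi; ++j)
                s += R::dgamma(lam[j], sh, 1.0 / rt, 1);
            return s;
        };
        double *hyp[4] = {&aT, &bT, &aF, &bF};
        for (int h = 0; h < 4; ++h) {
            int pidx = 9 + h;
            attempt[pidx] += 1.0;
            double cur = *hyp[h];
            double prop = cur * std::exp(propSd * norm_rand());
            if (prop > C) continue;
            double shC = aT, rtC = bT, shP = aT, rtP = bT;
            int lo = 0, hi = 6;
            if (h < 2) { shP = (h == 0) ? prop : aT;
                         rtP = (h == 1) ? prop : bT; }
            else { shC = aF; rtC = bF; lo = 7; hi = 8;
                   shP = (h == 2) ? prop : aF;
                   rtP = (h == 3) ? prop : bF; }
            double lacc = gammaSetLik(shP, rtP, lo, hi) -
                          gammaSetLik(shC, rtC, lo, hi) +
                          std::log(prop / cur);
            if (std::log(unif_rand()) < lacc) {
                *hyp[h] = prop;
                accept[pidx] += 1.0;
            }
        }

        // --- eta MH on the collapsed target:
        //     sum_i [ log alpha_{i, z_i} - log(eta B_i + alpha5) ]
        if (covariate) {
            attempt[13] += 1.0;
            double prop = reflectProp(eta, etaHw, E);
            double lacc = nScaled * (std::log(prop) - std::log(eta));
            for (int i = 0; i < n; ++i)
                lacc -= std::log(prop * Bi[i] + alpha5) -
                        std::log(eta * Bi[i] + alpha5);
            if (std::log(unif_rand()) < lacc) {
                eta = prop;
                accept[13] += 1.0;
            }
        }

        if (iter >= burnIn && (iter - burnIn) % thin == 0 &&
            drawRow < nDraw) {
            for (int j = 0; j < 9; ++j) draws(drawRow, j) = lam[j];
            draws(drawRow, 9) = aT; draws(drawRow, 10) = bT;
            draws(drawRow, 11) = aF; draws(drawRow, 12) = bF;
            draws(drawRow, 13) = eta;
            drawRow++;
        }
        if ((iter & 2047) == 0) Rcpp::checkUserInterrupt();
    }

    NumericMatrix post(n, K);
    double tot = (nIter > burnIn) ? double(nIter - burnIn) : 1.0;
    for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k)
            post(i, k) = zcount(i, k) / tot;
    NumericVector acc(nPar);
    for (int p = 0; p < nPar; ++p)
        acc[p] = attempt[p] > 0 ? accept[p] / attempt[p] : NA_REAL;
    return List::create(_["posterior"] = post,
                        _["draws"] = draws,
                        _["acceptance"] = acc);
}

// -------------------------------------------------------------- threecomp

static bool threecompOk(const double *l) {
    for (int j = 0; j < 5; ++j)
        if (!(l[j] > 0.0) || !std::isfinite(l[j])) return false;
    return l[0] > l[1] && l[3] < l[4];
}

static void threecompRates(const double *l, double *la, double *lb) {
    la[0] = l[0]; lb[0] = l[1];
    la[1] = l[2]; lb[1] = l[2];
    la[2] = l[3]; lb[2] = l[4];
}

// [[Rcpp::export]]
List cpp_run_threecomp(IntegerMatrix X, int T, NumericMatrix base,
                       bool covariate, NumericVector lamInit,
                       double a0, double b0, double eta0,
                       int nIter, int burnIn, int thin,
                       double propSd, double etaHw, double C, double D) {
    const int n = X.nrow(), K = 3;
    double lam[5];
    for (int j = 0; j < 5; ++j) lam[j] = lamInit[j];
    if (!threecompOk(lam)) stop("initial intensities violate the constraints");
    double a = a0, b = b0, eta = eta0;

    double la[3], lb[3], lz[3];
    threecompRates(lam, la, lb);
    for (int k = 0; k < K; ++k)
        lz[k] = logUpper(la[k], T) + logUpper(lb[k], T);

    // collapsed weights: all alphas eta-scaled, so only the normalized
    // base shares matter for z; eta's conditional is its (flat) prior
    std::vector<double> logShare(static_cast<size_t>(n) * K);
    for (int i = 0; i < n; ++i) {
        double s = base(i, 0) + base(i, 1) + base(i, 2);
        for (int k = 0; k < K; ++k)
            logShare[static_cast<size_t>(i) * K + k] =
                std::log(base(i, k) / s);
    }

    std::vector<int> z(n, 1);
    std::vector<double> sharedLogpi(K, std::log(1.0 / K));

    IntegerMatrix zcount(n, K);
    const int nDraw = (nIter > burnIn) ? (nIter - burnIn + thin - 1) / thin : 0;
    NumericMatrix draws(nDraw, 8);
    int drawRow = 0;
    const int nPar = 8; // 5 lams, a, b, eta
    std::vector<double> accept(nPar, 0.0), attempt(nPar, 0.0);
    double nk[3], S1[3], S2[3];

    for (int iter = 0; iter < nIter; ++iter) {
        double c1[3], c2[3], c0[3];
        for (int k = 0; k < K; ++k) {
            c1[k] = std::log(la[k]);
            c2[k] = std::log(lb[k]);
            c0[k] = -(la[k] + lb[k]) - lz[k];
        }
        for (int k = 0; k < K; ++k) { nk[k] = 0; S1[k] = 0; S2[k] = 0; }
        for (int i = 0; i < n; ++i) {
            const double *lp = covariate ?
                &logShare[static_cast<size_t>(i) * K] : sharedLogpi.data();
            double lw[3];
            double x1 = X(i, 0), x2 = X(i, 1);
            for (int k = 0; k < K; ++k)
                lw[k] = lp[k] + x1 * c1[k] + x2 * c2[k] + c0[k];
            int zi = drawCat(lw, K);
            z[i] = zi;
            nk[zi] += 1.0; S1[zi] += x1; S2[zi] += x2;
            if (iter >= burnIn) zcount(i, zi)++;
        }

        if (!covariate) {
            double g[3], s = 0.0;
            for (int k = 0; k < K; ++k) {
                g[k] = R::rgamma(1.0 + nk[k], 1.0) + 1e-300;
                s += g[k];
            }
            for (int k = 0; k < K; ++k)
                sharedLogpi[k] = std::log(clampProb(g[k] / s));
        }

        static const int compOf[5] = {0, 0, 1, 2, 2};
        for (int j = 0; j < 5; ++j) {
            attempt[j] += 1.0;
            double cur = lam[j];
            double prop = cur * std::exp(propSd * norm_rand());
            double lamNew[5];
            for (int q = 0; q < 5; ++q) lamNew[q] = lam[q];
            lamNew[j] = prop;
            if (!threecompOk(lamNew)) continue;
            double laN[3], lbN[3];
            threecompRates(lamNew, laN, lbN);
            int k = compOf[j];
            double lzN = logUpper(laN[k], T) + logUpper(lbN[k], T);
            double dlik =
                compLikStats(S1[k], S2[k], nk[k], laN[k], lbN[k], lzN) -
                compLikStats(S1[k], S2[k], nk[k], la[k], lb[k], lz[k]);
            double dpri = R::dgamma(prop, a, 1.0 / b, 1) -
                          R::dgamma(cur,  a, 1.0 / b, 1);
            double lacc = dlik + dpri + std::log(prop / cur);
            if (std::log(unif_rand()) < lacc) {
                lam[j] = prop;
                threecompRates(lam, la, lb);
                lz[k] = logUpper(la[k], T) + logUpper(lb[k], T);
                accept[j] += 1.0;
            }
        }

        double *hyp[2] = {&a, &b};
        for (int h = 0; h < 2; ++h) {
            int pidx = 5 + h;
            attempt[pidx] += 1.0;
            double cur = *hyp[h];
            double prop = cur * std::exp(propSd * norm_rand());
            if (prop > C) continue;
            double shP = (h == 0) ? prop : a;
            double rtP = (h == 1) ? prop : b;
            double lacc = std::log(prop / cur);
            for (int j = 0; j < 5; ++j)
                lacc += R::dgamma(lam[j], shP, 1.0 / rtP, 1) -
                        R::dgamma(lam[j], a, 1.0 / b, 1);
            if (std::log(unif_rand()) < lacc) {
                *hyp[h] = prop;
                accept[pidx] += 1.0;
            }
        }

        // eta: with every alpha eta-scaled the collapsed conditional is
        // the flat prior on (0, D]; the reflected-uniform move samples it
        if (covariate) {
            attempt[7] += 1.0;
            eta = reflectProp(eta, etaHw, D);
            accept[7] += 1.0;
        }

        if (iter >= burnIn && (iter - burnIn) % thin == 0 &&
            drawRow < nDraw) {
            for (int j = 0; j < 5; ++j) draws(drawRow, j) = lam[j];
            draws(drawRow, 5) = a; draws(drawRow, 6) = b;
            draws(drawRow, 7) = eta;
            drawRow++;
        }
        if ((iter & 2047) == 0) Rcpp::checkUserInterrupt();
    }

    NumericMatrix post(n, K);
    double tot = (nIter > burnIn) ? double(nIter - burnIn) : 1.0;
    for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k)
            post(i, k) = zcount(i, k) / tot;
    NumericVector acc(nPar);
    for (int p = 0; p < nPar; ++p)
        acc[p] = attempt[p] > 0 ? accept[p] / attempt[p] : NA_REAL;
    return List::create(_["posterior"] = post,
                        _["draws"] = draws,
                        _["acceptance"] = acc);
}

// ----------------------------------------------------------------- mcdist

// [[Rcpp::export]]
List cpp_run_mcdist(IntegerVector x, int T, NumericVector rbase,
                    double lamT0, double lamF0, double a0, double b0,
                    double eta0, int nIter, int burnIn, int thin,
                    double propSd, double etaHw, double C, double E) {
    const int n = x.size();
    double lamT = lamT0, lamF = lamF0, a = a0, b = b0, eta = eta0;
    if (!(lamT > lamF && lamF > 0))
        stop("initial intensities violate lamT > lamF > 0");

    std::vector<double> logw(n), log1mw(n);
    std::vector<int> z(n);
    for (int i = 0; i < n; ++i) {
        logw[i] = std::log(0.5); log1mw[i] = std::log(0.5);
        double lwT = x[i] * std::log(lamT) - lamT - logUpper(lamT, T);
        double lwF = x[i] * std::log(lamF) - lamF - logUpper(lamF, T);
        z[i] = lwT > lwF ? 1 : 0;
    }

    IntegerVector trueCount(n);
    const int nDraw = (nIter > burnIn) ? (nIter - burnIn + thin - 1) / thin : 0;
    NumericMatrix draws(nDraw, 5);
    int drawRow = 0;
    const int nPar = 5; // lamT lamF a b eta
    std::vector<double> accept(nPar, 0.0), attempt(nPar, 0.0);

    for (int iter = 0; iter < nIter; ++iter) {
        // z sweep
        double cT1 = std::log(lamT), cT0 = -lamT - logUpper(lamT, T);
        double cF1 = std::log(lamF), cF0 = -lamF - logUpper(lamF, T);
        double nT = 0.0, ST = 0.0, nF = 0.0, SF = 0.0;
        for (int i = 0; i < n; ++i) {
            double lw[2];
            lw[0] = log1mw[i] + x[i] * cF1 + cF0;
            lw[1] = logw[i] + x[i] * cT1 + cT0;
            int zi = drawCat(lw, 2);
            z[i] = zi;
            if (zi == 1) { nT += 1.0; ST += x[i]; }
            else { nF += 1.0; SF += x[i]; }
            if (iter >= burnIn && zi == 1) trueCount[i]++;
        }

        // w sweep (conjugate beta) and eta sufficient stat
        double Sw = 0.0;
        for (int i = 0; i < n; ++i) {
            double w = R::rbeta(eta * rbase[i] + (z[i] == 1 ? 1.0 : 0.0),
                                1.0 + (z[i] == 0 ? 1.0 : 0.0));
            w = clampProb(w);
            logw[i] = std::log(w);
            log1mw[i] = std::log1p(-w);
            Sw += rbase[i] * logw[i];
        }

        // intensity MH
        for (int j = 0; j < 2; ++j) {
            attempt[j] += 1.0;
            double cur = (j == 0) ? lamT : lamF;
            double prop = cur * std::exp(propSd * norm_rand());
            double pT = (j == 0) ? prop : lamT;
            double pF = (j == 1) ? prop : lamF;
            if (!(pT > pF && pF > 0)) continue;
            double dlik;
            if (j == 0)
                dlik = ST * std::log(pT) - nT * pT - nT * logUpper(pT, T) -
                       (ST * std::log(lamT) - nT * lamT -
                        nT * logUpper(lamT, T));
            else
                dlik = SF * std::log(pF) - nF * pF - nF * logUpper(pF, T) -
                       (SF * std::log(lamF) - nF * lamF -
                        nF * logUpper(lamF, T));
            double dpri = R::dgamma(prop, a, 1.0 / b, 1) -
                          R::dgamma(cur,  a, 1.0 / b, 1);
            double lacc = dlik + dpri + std::log(prop / cur);
            if (std::log(unif_rand()) < lacc) {
                if (j == 0) lamT = prop; else lamF = prop;
                accept[j] += 1.0;
            }
        }

        // hyper MH
        double *hyp[2] = {&a, &b};
        for (int h = 0; h < 2; ++h) {
            int pidx = 2 + h;
            attempt[pidx] += 1.0;
            double cur = *hyp[h];
            double prop = cur * std::exp(propSd * norm_rand());
            if (prop > C) continue;
            double shP = (h == 0) ? prop : a;
            double rtP = (h == 1) ? prop : b;
            double lacc = std::log(prop / cur) +
                R::dgamma(lamT, shP, 1.0 / rtP, 1) +
                R::dgamma(lamF, shP, 1.0 / rtP, 1) -
                R::dgamma(lamT, a, 1.0 / b, 1) -
                R::dgamma(lamF, a, 1.0 / b, 1);
            if (std::log(unif_rand()) < lacc) {
                *hyp[h] = prop;
                accept[pidx] += 1.0;
            }
        }

        // eta MH: Beta(eta*r, 1) density product over the sampled weights
        {
            attempt[4] += 1.0;
            double prop = reflectProp(eta, etaHw, E);
            double lacc = n * (std::log(prop) - std::log(eta)) +
                          (prop - eta) * Sw;
            if (std::log(unif_rand()) < lacc) {
                eta = prop;
                accept[4] += 1.0;
            }
        }

        if (iter >= burnIn && (iter - burnIn) % thin == 0 &&
            drawRow < nDraw) {
            draws(drawRow, 0) = lamT; draws(drawRow, 1) = lamF;
            draws(drawRow, 2) = a; draws(drawRow, 3) = b;
            draws(drawRow, 4) = eta;
            drawRow++;
        }
        if ((iter & 4095) == 0) Rcpp::checkUserInterrupt();
    }

    double tot = (nIter > burnIn) ? double(nIter - burnIn) : 1.0;
    NumericVector pTrue(n);
    for (int i = 0; i < n; ++i) pTrue[i] = trueCount[i] / tot;
    NumericVector acc(nPar);
    for (int p = 0; p < nPar; ++p)
        acc[p] = attempt[p] > 0 ? accept[p] / attempt[p] : NA_REAL;
    return List::create(_["posteriorTrue"] = pTrue,
                        _["draws"] = draws,
                        _["acceptance"] = acc);
}
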