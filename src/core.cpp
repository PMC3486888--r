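// Compiled core of the hybrid simulator: off-lattice 3-D agent-based model
// of tumor cells and CTLs, the per-step lymph-node difference system, and
// the coupled driver. All randomness is drawn from R's RNG stream so that
// set.seed() fully determines a run.
//
// Units: lengths um, ABM step dt in minutes, lymph-node rates per day with
// the step expressed in days; concentrations 1e3 cells/mm^3.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

static const double TSTOP_FULL = 1e300; // "at full speed" sentinel (maps Inf)

struct P {
  double dt, dtDays, rCell, rRoi, wCloud, sigmaMax, tAccelMin;
  double pDiv, pDeath, pRecr, pKill, vCloud;
  double sA, a0, deltaA, deltaMA, rhoM, mEq, b, g, deltaE, aAnt, rVol, twoN;
  int kProg, kDiv;
};

static P parseP(const List& cp) {
  P p;
  p.dt = cp["dt"]; p.dtDays = cp["dtDays"]; p.rCell = cp["rCell"];
  p.rRoi = cp["rRoi"]; p.wCloud = cp["wCloud"]; p.sigmaMax = cp["sigmaMax"];
  p.tAccelMin = cp["tAccelMin"];
  p.pDiv = cp["pDiv"]; p.pDeath = cp["pDeath"]; p.pRecr = cp["pRecr"];
  p.pKill = cp["pKill"]; p.vCloud = cp["vCloud"];
  p.sA = cp["sA"]; p.a0 = cp["a0"];
  p.deltaA = cp["deltaA"]; p.deltaMA = cp["deltaMA"];
  p.rhoM = cp["rhoM"]; p.mEq = cp["mEq"]; p.b = cp["b"]; p.g = cp["g"];
  p.deltaE = cp["deltaE"]; p.aAnt = cp["aAnt"]; p.rVol = cp["rVol"];
  p.twoN = cp["twoN"]; p.kProg = cp["kProg"]; p.kDiv = cp["kDiv"];
  return p;
}

// ---------------------------------------------------------------- lymph node

struct LN {
  double A, MA, M, E, Et;
  long k;
  int L;
  std::vector<double> hM, hMA, hE;

  void init(const P& p) {
    A = 0; // caller sets A0
    MA = 0; M = p.mEq; E = 0; Et = 0; k = 0;
    L = std::max(p.kProg, p.kDiv) + 1;
    hM.assign(L, p.mEq); hMA.assign(L, 0.0); hE.assign(L, 0.0);
  }
  inline double atM(long kk) const { return hM[((kk % L) + L) % L]; }
  inline double atMA(long kk) const { return hMA[((kk % L) + L) % L]; }
  inline double atE(long kk) const { return hE[((kk % L) + L) % L]; }

  void step(const P& p, double Tk) {
    const double dt = p.dtDays;
    const double survA = std::exp(-p.deltaA * dt);
    const double stimA = -std::expm1(-p.aAnt * Tk * dt);
    const double Anew = (p.sA / p.deltaA) * (-std::expm1(-p.deltaA * dt)) +
      survA * (1.0 - stimA) * A;
    const double MAnew = p.rVol * survA * stimA * A +
      std::exp(-p.deltaMA * dt) * MA;

    const double pAct = -std::expm1(-p.b * MA * dt);
    const double Mnew = M - pAct * M + p.rhoM * M * (1.0 - M / p.mEq) * dt;

    const double MAp = atMA(k - p.kProg), Mp = atM(k - p.kProg);
    const double MAd = atMA(k - p.kDiv), Ed = atE(k - p.kDiv);
    const double sE = std::exp(-p.deltaE * dt);
    const double pG = -std::expm1(-p.g * dt);
    const double pActP = -std::expm1(-p.b * MAp * dt);
    const double pActD = -std::expm1(-p.b * MAd * dt);
    const double Enew = p.twoN * pActP * Mp +
      sE * (1.0 - pAct) * (1.0 - pG) * E +
      2.0 * sE * pActD * Ed;
    const double EtNew = sE * Et + (1.0 / p.rVol) * sE * (1.0 - pAct) * pG * E;

    ++k;
    const int slot = (int)(k % L);
    hM[slot] = Mnew; hMA[slot] = MAnew; hE[slot] = Enew;
    A = Anew; MA = MAnew; M = Mnew; E = Enew; Et = EtNew;
  }
};

// [[Rcpp::export]]
NumericMatrix ln_run_cpp(List cp, NumericVector Tvec) {
  P p = parseP(cp);
  LN ln; ln.init(p);
  ln.A = p.a0;
  const int n = Tvec.size();
  NumericMatrix out(n + 1, 5);
  out(0, 0) = ln.A; out(0, 1) = ln.MA; out(0, 2) = ln.M;
  out(0, 3) = ln.E; out(0, 4) = ln.Et;
  for (int i = 0; i < n; ++i) {
    ln.step(p, Tvec[i]);
    out(i + 1, 0) = ln.A; out(i + 1, 1) = ln.MA; out(i + 1, 2) = ln.M;
    out(i + 1, 3) = ln.E; out(i + 1, 4) = ln.Et;
  }
  return out;
}

// --------------------------------------------------------------- tumor site

struct Agent {
  double x, y, z;
  double tstop;   // minutes since the CTL last started moving
  int target;     // CTL: agent index of engaged tumor cell, -1 if moving
  int id;
  int type;       // 0 = tumor, 1 = CTL
  bool alive;
};

struct Grid {
  double h, ext;
  int n;                       // cells per dimension
  std::vector<int> head;       // n^3 cell heads (-1 empty)
  std::vector<int> nxt;        // per-agent chain
  std::vector<int> cellOf;     // per-agent cell (-1 = not inserted)

  void init(double extent, double cellSize, int capacity) {
    ext = extent; h = cellSize;
    n = std::max(1, (int)std::ceil(2.0 * ext / h));
    head.assign((size_t)n * n * n, -1);
    nxt.assign(capacity, -1);
    cellOf.assign(capacity, -1);
  }
  inline int clampc(int c) const { return c < 0 ? 0 : (c >= n ? n - 1 : c); }
  inline int coord(double v) const { return clampc((int)std::floor((v + ext) / h)); }
  inline int cellIndex(double x, double y, double z) const {
    return (coord(x) * n + coord(y)) * n + coord(z);
  }
  void ensure(int capacity) {
    if ((int)nxt.size() < capacity) { nxt.resize(capacity, -1); cellOf.resize(capacity, -1); }
  }
  void insert(int i, double x, double y, double z) {
    ensure(i + 1);
    int c = cellIndex(x, y, z);
    nxt[i] = head[c]; head[c] = i; cellOf[i] = c;
  }
  void remove(int i) {
    int c = cellOf[i];
    if (c < 0) return;
    int j = head[c];
    if (j == i) head[c] = nxt[i];
    else {
      while (j >= 0 && nxt[j] != i) j = nxt[j];
      if (j >= 0) nxt[j] = nxt[i];
    }
    cellOf[i] = -1; nxt[i] = -1;
  }
  void move(int i, double x, double y, double z) {
    int c = cellIndex(x, y, z);
    if (c != cellOf[i]) { remove(i); insert(i, x, y, z); }
  }
};

struct Site {
  std::vector<Agent> ag;
  std::vector<int> freeSlots;
  Grid grid;
  long step;
  int nextTumorId, nextCtlId;
  int nTumor = 0, nCtl = 0;
  const P* p;

  void setup(const P& pp) {
    p = &pp;
    double extent = pp.rRoi + pp.wCloud + 8.0 * pp.sigmaMax * std::sqrt(pp.dt)
      + 4.0 * pp.rCell;
    // cap grid dimensions at 256^3 cells for very large domains
    double cs = std::max(std::max(2.0 * pp.rCell, 1e-6), 2.0 * extent / 256.0);
    grid.init(extent, cs, (int)ag.size() + 64);
    for (int i = 0; i < (int)ag.size(); ++i)
      if (ag[i].alive) grid.insert(i, ag[i].x, ag[i].y, ag[i].z);
  }

  int addAgent(const Agent& a) {
    int i;
    if (!freeSlots.empty()) { i = freeSlots.back(); freeSlots.pop_back(); ag[i] = a; }
    else { i = (int)ag.size(); ag.push_back(a); }
    grid.ensure((int)ag.size() + 1);
    grid.insert(i, a.x, a.y, a.z);
    (a.type == 0 ? nTumor : nCtl)++;
    return i;
  }
  void killAgent(int i) {
    ag[i].alive = false;
    grid.remove(i);
    freeSlots.push_back(i);
    (ag[i].type == 0 ? nTumor : nCtl)--;
  }

  int tumorCount() const { return nTumor; }
  int ctlCount() const { return nCtl; }
  int engagedCount() const {
    int c = 0;
    for (const Agent& a : ag) if (a.alive && a.type == 1 && a.target >= 0) ++c;
    return c;
  }

  // any live agent (other than `skip`) with centre strictly closer than minDist?
  bool overlapsAny(double x, double y, double z, double minDist, int skip = -1) const {
    const double m2 = minDist * minDist;
    const Grid& g = grid;
    int cx0 = g.coord(x - minDist), cx1 = g.coord(x + minDist);
    int cy0 = g.coord(y - minDist), cy1 = g.coord(y + minDist);
    int cz0 = g.coord(z - minDist), cz1 = g.coord(z + minDist);
    for (int cx = cx0; cx <= cx1; ++cx)
      for (int cy = cy0; cy <= cy1; ++cy)
        for (int cz = cz0; cz <= cz1; ++cz) {
          int j = g.head[((size_t)cx * g.n + cy) * g.n + cz];
          while (j >= 0) {
            if (j != skip && ag[j].alive) {
              double dx = ag[j].x - x, dy = ag[j].y - y, dz = ag[j].z - z;
              if (dx * dx + dy * dy + dz * dz < m2) return true;
            }
            j = g.nxt[j];
          }
        }
    return false;
  }

  // uniform random unit vector
  static void unitVec(double& ux, double& uy, double& uz) {
    double n2;
    do {
      ux = norm_rand(); uy = norm_rand(); uz = norm_rand();
      n2 = ux * ux + uy * uy + uz * uz;
    } while (n2 < 1e-12);
    double inv = 1.0 / std::sqrt(n2);
    ux *= inv; uy *= inv; uz *= inv;
  }

  // tangent placement in a uniformly sampled unoccupied direction;
  // rejection-sampled with a fixed attempt cap (no-space on failure)
  bool placeTangent(double px, double py, double pz, bool confineRoi,
                    double& ox, double& oy, double& oz) {
    const double d = 2.0 * p->rCell;
    const double minDist = d - 1e-7;
    for (int att = 0; att < 50; ++att) {
      double ux, uy, uz;
      unitVec(ux, uy, uz);
      double x = px + d * ux, y = py + d * uy, z = pz + d * uz;
      if (confineRoi) {
        double rr = std::sqrt(x * x + y * y + z * z);
        if (rr + p->rCell > p->rRoi) continue;
      }
      if (overlapsAny(x, y, z, minDist)) continue;
      ox = x; oy = y; oz = z;
      return true;
    }
    return false;
  }

  // -------------------------------------------------------------- phases

  void spawnCloud(double eTiss) {
    if (eTiss < 0 || !std::isfinite(eTiss))
      stop("E_tiss must be a finite nonnegative concentration");
    double lam = eTiss * 1e3 * p->vCloud;
    if (lam <= 0) return;
    int N = (int)R::rpois(lam);
    const double R0 = p->rRoi, R1 = p->rRoi + p->wCloud;
    const double R03 = R0 * R0 * R0, R13 = R1 * R1 * R1;
    const double minDist = 2.0 * p->rCell - 1e-7;
    for (int s = 0; s < N; ++s) {
      for (int att = 0; att < 50; ++att) {
        double rad = std::cbrt(R03 + unif_rand() * (R13 - R03));
        double ux, uy, uz;
        unitVec(ux, uy, uz);
        double x = rad * ux, y = rad * uy, z = rad * uz;
        if (overlapsAny(x, y, z, minDist)) continue;
        Agent a; a.x = x; a.y = y; a.z = z; a.tstop = TSTOP_FULL;
        a.target = -1; a.id = nextCtlId++; a.type = 1; a.alive = true;
        addAgent(a);
        break;
      }
    }
  }

  void ctlDeath(double pDeath) {
    if (pDeath <= 0) return;
    const int n0 = (int)ag.size();
    for (int i = 0; i < n0; ++i)
      if (ag[i].alive && ag[i].type == 1 && unif_rand() < pDeath)
        killAgent(i);
  }

  void recruitKill(double pRecr, double pKill) {
    const int n0 = (int)ag.size();
    std::vector<int> engaged;
    engaged.reserve(64);
    for (int i = 0; i < n0; ++i)
      if (ag[i].alive && ag[i].type == 1 && ag[i].target >= 0)
        engaged.push_back(i);
    for (int i : engaged) {
      int t = ag[i].target;
      if (t < 0 || !ag[t].alive) continue; // target killed earlier this phase
      if (unif_rand() < pRecr) {
        double x, y, z;
        if (placeTangent(ag[i].x, ag[i].y, ag[i].z, false, x, y, z)) {
          Agent a; a.x = x; a.y = y; a.z = z; a.tstop = 0.0;
          a.target = -1; a.id = nextCtlId++; a.type = 1; a.alive = true;
          addAgent(a);
        }
      }
      if (unif_rand() < pKill) {
        killAgent(t);
        for (int j = 0; j < (int)ag.size(); ++j)
          if (ag[j].alive && ag[j].type == 1 && ag[j].target == t) {
            ag[j].target = -1;
            ag[j].tstop = 0.0; // disengaged CTLs re-accelerate from rest
          }
      }
    }
  }

  void divisions(double pDiv) {
    if (pDiv <= 0) return;
    // snapshot current tumor cells: daughters first divide next step
    std::vector<int> cells;
    cells.reserve(nTumor);
    for (int i = 0; i < (int)ag.size(); ++i)
      if (ag[i].alive && ag[i].type == 0) cells.push_back(i);
    for (int i : cells) {
      if (unif_rand() >= pDiv) continue;
      double x, y, z;
      if (placeTangent(ag[i].x, ag[i].y, ag[i].z, true, x, y, z)) {
        Agent a; a.x = x; a.y = y; a.z = z; a.tstop = 0.0;
        a.target = -1; a.id = nextTumorId++; a.type = 0; a.alive = true;
        addAgent(a);
      } // else: fully caged or at the boundary -> division fails
    }
  }

  // earliest contact along the segment pos -> pos + d with any other agent
  double firstContact(int i, double dx, double dy, double dz) const {
    const Agent& a = ag[i];
    const double D = 2.0 * p->rCell;
    const double D2 = D * D;
    double tmin = 1.0;
    const Grid& g = grid;
    double x1 = a.x + dx, y1 = a.y + dy, z1 = a.z + dz;
    double lx = std::min(a.x, x1) - D, hx = std::max(a.x, x1) + D;
    double ly = std::min(a.y, y1) - D, hy = std::max(a.y, y1) + D;
    double lz = std::min(a.z, z1) - D, hz = std::max(a.z, z1) + D;
    int cx0 = g.coord(lx), cx1 = g.coord(hx);
    int cy0 = g.coord(ly), cy1 = g.coord(hy);
    int cz0 = g.coord(lz), cz1 = g.coord(hz);
    const double qa = dx * dx + dy * dy + dz * dz;
    if (qa <= 0) return 1.0;
    for (int cx = cx0; cx <= cx1; ++cx)
      for (int cy = cy0; cy <= cy1; ++cy)
        for (int cz = cz0; cz <= cz1; ++cz) {
          int j = g.head[((size_t)cx * g.n + cy) * g.n + cz];
          while (j >= 0) {
            if (j != i && ag[j].alive) {
              double rx = a.x - ag[j].x, ry = a.y - ag[j].y, rz = a.z - ag[j].z;
              double qb = dx * rx + dy * ry + dz * rz;
              double qc = rx * rx + ry * ry + rz * rz - D2;
              if (qc <= 1e-9 * D2) {
                if (qb < 0) { tmin = 0.0; }
              } else {
                double disc = qb * qb - qa * qc;
                if (disc > 0 && qb < 0) {
                  double t = (-qb - std::sqrt(disc)) / qa;
                  if (t >= 0 && t < tmin) tmin = t;
                }
              }
            }
            j = g.nxt[j];
          }
        }
    return tmin;
  }

  void moveCtls() {
    std::vector<int> order;
    order.reserve(64);
    for (int i = 0; i < (int)ag.size(); ++i)
      if (ag[i].alive && ag[i].type == 1) order.push_back(i);
    // fresh random permutation of the visit order
    for (int k = (int)order.size() - 1; k > 0; --k) {
      int j = (int)std::floor(unif_rand() * (k + 1));
      if (j > k) j = k;
      std::swap(order[k], order[j]);
    }
    const double sq = std::sqrt(p->dt);
    for (int i : order) {
      Agent& a = ag[i];
      if (a.target >= 0) continue; // engaged CTLs do not move
      double frac = a.tstop >= p->tAccelMin ? 1.0 : a.tstop / p->tAccelMin;
      double sigma = frac * p->sigmaMax;
      if (sigma > 0) {
        double dx = sigma * sq * norm_rand();
        double dy = sigma * sq * norm_rand();
        double dz = sigma * sq * norm_rand();
        double t = firstContact(i, dx, dy, dz);
        if (t > 0) {
          a.x += t * dx; a.y += t * dy; a.z += t * dz;
          grid.move(i, a.x, a.y, a.z);
        }
      }
      a.tstop = std::min(a.tstop + p->dt, TSTOP_FULL);
    }
  }

  void updateEngagements() {
    const double reach = 2.0 * p->rCell + 1e-3 * p->rCell;
    for (int i = 0; i < (int)ag.size(); ++i) {
      Agent& a = ag[i];
      if (!a.alive || a.type != 1 || a.target >= 0) continue;
      const Grid& g = grid;
      int cx0 = g.coord(a.x - reach), cx1 = g.coord(a.x + reach);
      int cy0 = g.coord(a.y - reach), cy1 = g.coord(a.y + reach);
      int cz0 = g.coord(a.z - reach), cz1 = g.coord(a.z + reach);
      int best = -1, bestId = 0;
      double bestD2 = reach * reach;
      for (int cx = cx0; cx <= cx1; ++cx)
        for (int cy = cy0; cy <= cy1; ++cy)
          for (int cz = cz0; cz <= cz1; ++cz) {
            int j = g.head[((size_t)cx * g.n + cy) * g.n + cz];
            while (j >= 0) {
              if (ag[j].alive && ag[j].type == 0) {
                double dx = ag[j].x - a.x, dy = ag[j].y - a.y, dz = ag[j].z - a.z;
                double d2 = dx * dx + dy * dy + dz * dz;
                // nearest wins; near-exact ties broken by lowest id
                if (d2 < bestD2 - 1e-9 ||
                    (d2 < bestD2 + 1e-9 && (best < 0 || ag[j].id < bestId))) {
                  if (d2 <= reach * reach) {
                    best = j; bestId = ag[j].id; bestD2 = d2;
                  }
                }
              }
              j = g.nxt[j];
            }
          }
      if (best >= 0) {
        a.target = best;
        a.tstop = 0.0;
      }
    }
  }

  void cull() {
    const double R2 = p->rRoi * p->rRoi;
    for (int i = 0; i < (int)ag.size(); ++i) {
      Agent& a = ag[i];
      if (a.alive && a.type == 1 &&
          a.x * a.x + a.y * a.y + a.z * a.z > R2)
        killAgent(i);
    }
  }

  void stepOnce(double eTiss) {
    spawnCloud(eTiss);
    ctlDeath(p->pDeath);
    recruitKill(p->pRecr, p->pKill);
    divisions(p->pDiv);
    moveCtls();
    updateEngagements();
    cull();
    ++step;
  }
};

// ------------------------------------------------- R-side (de)serialization

static Site siteFromList(const List& sl, const P& p) {
  Site s;
  NumericMatrix tp = sl["tumorPos"];
  IntegerVector tid = sl["tumorId"];
  NumericMatrix cpos = sl["ctlPos"];
  NumericVector cts = sl["ctlTstop"];
  IntegerVector ctg = sl["ctlTarget"]; // tumor *ids*, NA = moving
  IntegerVector cid = sl["ctlId"];
  s.step = (long)as<double>(sl["step"]);
  s.nextTumorId = as<int>(sl["nextTumorId"]);
  s.nextCtlId = as<int>(sl["nextCtlId"]);
  std::map<int, int> id2idx;
  for (int i = 0; i < tp.nrow(); ++i) {
    Agent a; a.x = tp(i, 0); a.y = tp(i, 1); a.z = tp(i, 2);
    a.tstop = 0; a.target = -1; a.id = tid[i]; a.type = 0; a.alive = true;
    s.ag.push_back(a);
    s.nTumor++;
    id2idx[a.id] = (int)s.ag.size() - 1;
  }
  for (int i = 0; i < cpos.nrow(); ++i) {
    Agent a; a.x = cpos(i, 0); a.y = cpos(i, 1); a.z = cpos(i, 2);
    a.tstop = (cts[i] == R_PosInf) ? TSTOP_FULL : cts[i];
    a.target = -1;
    if (ctg[i] != NA_INTEGER) {
      std::map<int, int>::iterator it = id2idx.find(ctg[i]);
      if (it == id2idx.end()) stop("engaged CTL targets a missing tumor id");
      a.target = it->second;
    }
    a.id = cid[i]; a.type = 1; a.alive = true;
    s.ag.push_back(a);
    s.nCtl++;
  }
  s.setup(p);
  return s;
}

static List siteToList(const Site& s) {
  int nt = 0, nc = 0;
  for (const Agent& a : s.ag) if (a.alive) (a.type == 0 ? nt : nc)++;
  NumericMatrix tp(nt, 3), cpos(nc, 3);
  IntegerVector tid(nt), ctg(nc), cid(nc);
  NumericVector cts(nc);
  int it = 0, ic = 0;
  for (const Agent& a : s.ag) {
    if (!a.alive) continue;
    if (a.type == 0) {
      tp(it, 0) = a.x; tp(it, 1) = a.y; tp(it, 2) = a.z;
      tid[it] = a.id; ++it;
    } else {
      cpos(ic, 0) = a.x; cpos(ic, 1) = a.y; cpos(ic, 2) = a.z;
      cts[ic] = (a.tstop >= TSTOP_FULL) ? R_PosInf : a.tstop;
      ctg[ic] = (a.target >= 0) ? s.ag[a.target].id : NA_INTEGER;
      cid[ic] = a.id; ++ic;
    }
  }
  return List::create(
    _["tumorPos"] = tp, _["tumorId"] = tid,
    _["ctlPos"] = cpos, _["ctlTstop"] = cts, _["ctlTarget"] = ctg,
    _["ctlId"] = cid, _["step"] = (double)s.step,
    _["nextTumorId"] = s.nextTumorId, _["nextCtlId"] = s.nextCtlId);
}

// ------------------------------------------------------- exported phase API

// [[Rcpp::export]]
List abm_spawn_cpp(List cp, List site, double eTiss) {
  P p = parseP(cp);
  Site s = siteFromList(site, p);
  s.spawnCloud(eTiss);
  return siteToList(s);
}

// [[Rcpp::export]]
List abm_death_cpp(List cp, List site, double pDeath) {
  P p = parseP(cp);
  Site s = siteFromList(site, p);
  s.ctlDeath(pDeath);
  return siteToList(s);
}

// [[Rcpp::export]]
List abm_recruit_kill_cpp(List cp, List site, double pRecr, double pKill) {
  P p = parseP(cp);
  Site s = siteFromList(site, p);
  s.recruitKill(pRecr, pKill);
  return siteToList(s);
}

// [[Rcpp::export]]
List abm_divide_cpp(List cp, List site, double pDiv) {
  P p = parseP(cp);
  Site s = siteFromList(site, p);
  s.divisions(pDiv);
  return siteToList(s);
}

// [[Rcpp::export]]
List abm_move_cpp(List cp, List site) {
  P p = parseP(cp);
  Site s = siteFromList(site, p);
  s.moveCtls();
  return siteToList(s);
}

// [[Rcpp::export]]
List abm_engage_cpp(List cp, List site) {
  P p = parseP(cp);
  Site s = siteFromList(site, p);
  s.updateEngagements();
  return siteToList(s);
}

// [[Rcpp::export]]
List abm_cull_cpp(List cp, List site) {
  P p = parseP(cp);
  Site s = siteFromList(site, p);
  s.cull();
  return siteToList(s);
}

// [[Rcpp::export]]
List abm_step_cpp(List cp, List site, double eTiss) {
  P p = parseP(cp);
  Site s = siteFromList(site, p);
  s.stepOnce(eTiss);
  return siteToList(s);
}

// ------------------------------------------------------------ hybrid driver

// Coupled run. Synchronous exchange: the lymph node consumes the pre-step
// tumor count while the ABM consumes the pre-step tissue concentration.
// If useLn is false the site sees the constant eTissConst instead.
// [[Rcpp::export]]
List run_hybrid_cpp(List cp, List site, long maxSteps, int thinSteps,
                    bool stopOnExtinction, bool useLn, double eTissConst) {
  P p = parseP(cp);
  Site s = siteFromList(site, p);
  LN ln; ln.init(p);
  ln.A = p.a0;
  if (thinSteps < 1) thinSteps = 1;

  std::vector<double> rows;
  rows.reserve(9 * (size_t)(maxSteps / thinSteps + 2));
  long extinctionStep = -1;
  int tumorNow = s.tumorCount();
  double maxTumor = tumorNow;
  long tMaxStep = 0;

  auto record = [&](long k) {
    rows.push_back(k * p.dtDays);
    rows.push_back(s.tumorCount());
    rows.push_back(s.ctlCount());
    rows.push_back(s.engagedCount());
    rows.push_back(ln.A); rows.push_back(ln.MA); rows.push_back(ln.M);
    rows.push_back(ln.E); rows.push_back(ln.Et);
  };

  long k = 0;
  for (; k < maxSteps; ++k) {
    if (k % thinSteps == 0) record(k);
    double Tk = tumorNow;
    double eT = useLn ? ln.Et : eTissConst;
    s.stepOnce(eT);
    if (useLn) ln.step(p, Tk);
    tumorNow = s.tumorCount();
    if (tumorNow > maxTumor) { maxTumor = tumorNow; tMaxStep = k + 1; }
    if (tumorNow == 0 && extinctionStep < 0) {
      extinctionStep = k + 1;
      if (stopOnExtinction) { ++k; break; }
    }
    if (k % 2048 == 0) Rcpp::checkUserInterrupt();
  }
  record(k);

  int nr = (int)(rows.size() / 9);
  NumericMatrix series(nr, 9);
  for (int r = 0; r < nr; ++r)
    for (int cidx = 0; cidx < 9; ++cidx)
      series(r, cidx) = rows[(size_t)r * 9 + cidx];

  return List::create(
    _["series"] = series,
    _["extinctionStep"] = (double)extinctionStep,
    _["maxTumor"] = maxTumor,
    _["tMaxStep"] = (double)tMaxStep,
    _["finalSite"] = siteToList(s),
    _["lnFinal"] = NumericVector::create(ln.A, ln.MA, ln.M, ln.E, ln.Et));
}

// ------------------------------------------------------ surface-kill model

struct SurfP {
  double kappaG, kappaIn, dTumDays, dKillDays, dRecrDays, deltaE, rCell;
};

// d/dt of (T, Es) in days; surface-limited growth and kill
static inline void surfRhs(const SurfP& s, double T, double Es, double eTiss,
                           double& dT, double& dEs) {
  if (T < 0) T = 0;
  double T23 = std::pow(T, 2.0 / 3.0);
  double Emax = 4.0 * T23;
  double Rt = s.rCell * std::cbrt(T);
  double shellOut = Rt + 2.0 * s.rCell;
  double Vshell = (4.0 * M_PI / 3.0) *
    (shellOut * shellOut * shellOut - Rt * Rt * Rt) * 1e-9; // mm^3
  double dens = Emax > 0 ? (1.0 - Es / Emax) : 0.0;
  double kill = (Emax > 0 ? std::min(Es, Emax) : 0.0) / s.dKillDays;
  dT = s.kappaG * 4.0 * T23 / s.dTumDays - kill;
  if (T <= 0 && dT < 0) dT = 0;
  dEs = s.kappaIn * (eTiss * 1e3 * Vshell) * dens - s.deltaE * Es +
    (Es / s.dRecrDays) * dens;
}

// [[Rcpp::export]]
List run_surface_cpp(List cp, List sp, long maxSteps, int thinSteps) {
  P p = parseP(cp);
  SurfP s;
  s.kappaG = sp["kappaG"]; s.kappaIn = sp["kappaIn"];
  s.dTumDays = sp["dTumDays"]; s.dKillDays = sp["dKillDays"];
  s.dRecrDays = sp["dRecrDays"]; s.deltaE = p.deltaE; s.rCell = p.rCell;
  LN ln; ln.init(p);
  ln.A = p.a0;
  if (thinSteps < 1) thinSteps = 1;
  double T = 1.0, Es = 0.0;
  double extinction = -1.0;
  const double dt = p.dtDays;
  std::vector<double> rows;
  rows.reserve(4 * (size_t)(maxSteps / thinSteps + 2));
  auto record = [&](long k) {
    rows.push_back(k * dt); rows.push_back(T); rows.push_back(Es);
    rows.push_back(ln.Et);
  };
  for (long k = 0; k < maxSteps; ++k) {
    if (k % thinSteps == 0) record(k);
    double Tk = T, eT = ln.Et;
    if (T > 0) {
      // classical RK4 on (T, Es) with eT frozen over the step
      double k1T, k1E, k2T, k2E, k3T, k3E, k4T, k4E;
      surfRhs(s, T, Es, eT, k1T, k1E);
      surfRhs(s, T + 0.5 * dt * k1T, Es + 0.5 * dt * k1E, eT, k2T, k2E);
      surfRhs(s, T + 0.5 * dt * k2T, Es + 0.5 * dt * k2E, eT, k3T, k3E);
      surfRhs(s, T + dt * k3T, Es + dt * k3E, eT, k4T, k4E);
      double Tn = T + dt / 6.0 * (k1T + 2 * k2T + 2 * k3T + k4T);
      double En = Es + dt / 6.0 * (k1E + 2 * k2E + 2 * k3E + k4E);
      if (Tn <= 0) {
        // event location by linear interpolation inside the step
        double frac = T / (T - Tn);
        if (!std::isfinite(frac) || frac < 0) frac = 0;
        if (frac > 1) frac = 1;
        extinction = (k + frac) * dt;
        Tn = 0.0; // absorbing thereafter
      }
      T = Tn;
      Es = En < 0 ? 0 : En;
      if (T > 0) {
        double Emax = 4.0 * std::pow(T, 2.0 / 3.0);
        if (Es > Emax) Es = Emax; // numerical-safety clamp at capacity
      }
    } else {
      Es *= std::exp(-s.deltaE * dt); // dispersal/death after extinction
    }
    ln.step(p, Tk);
    if (k % 8192 == 0) Rcpp::checkUserInterrupt();
  }
  record(maxSteps);
  int nr = (int)(rows.size() / 4);
  NumericMatrix series(nr, 4);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < 4; ++c) series(r, c) = rows[(size_t)r * 4 + c];
  return List::create(_["series"] = series, _["extinctionTime"] = extinction);
}

// -------------------------------------------------- neighbor-search oracle

// all unordered pairs with centre distance <= radius, via the uniform grid
// (compared against brute force in the tests)
// [[Rcpp::export]]
IntegerMatrix neighbor_pairs_cpp(NumericMatrix pos, double radius) {
  int n = pos.nrow();
  double ext = 1.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j)
      ext = std::max(ext, std::fabs(pos(i, j)) + radius);
  Grid g;
  g.init(ext, std::max(std::max(radius, 1e-6), 2.0 * ext / 256.0), n);
  for (int i = 0; i < n; ++i) g.insert(i, pos(i, 0), pos(i, 1), pos(i, 2));
  std::vector<int> ai, bi;
  const double r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    int cx0 = g.coord(pos(i, 0) - radius), cx1 = g.coord(pos(i, 0) + radius);
    int cy0 = g.coord(pos(i, 1) - radius), cy1 = g.coord(pos(i, 1) + radius);
    int cz0 = g.coord(pos(i, 2) - radius), cz1 = g.coord(pos(i, 2) + radius);
    for (int cx = cx0; cx <= cx1; ++cx)
      for (int cy = cy0; cy <= cy1; ++cy)
        for (int cz = cz0; cz <= cz1; ++cz) {
          int j = g.head[((size_t)cx * g.n + cy) * g.n + cz];
          while (j >= 0) {
            if (j > i) {
              double dx = pos(i, 0) - pos(j, 0);
              double dy = pos(i, 1) - pos(j, 1);
              double dz = pos(i, 2) - pos(j, 2);
              if (dx * dx + dy * dy + dz * dz <= r2) {
                ai.push_back(i + 1); bi.push_back(j + 1);
              }
            }
            j = g.nxt[j];
          }
        }
  }
  IntegerMatrix out((int)ai.size(), 2);
  for (int r = 0; r < (int)ai.size(); ++r) { out(r, 0) = ai[r]; out(r, 1) = bi[r]; }
  return out;
}
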