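// Gillespie-type kinetic Monte Carlo engine for microfibril saccharification.
//
// Markovian channels (EG cut, XYL cut, BGL cleavage, CBH attachment, CBH step,
// lignin adhesion) are drawn with the direct method; CBH detachment deadlines
// (normally distributed residence times) live in a priority queue and preempt
// the exponential draw when earlier.  Per-bond digestion weights are held in
// Fenwick trees so selection and local updates are O(log n).  All randomness
// comes from R's RNG, so runs are reproducible under set.seed().

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();

// Fenwick tree with real weights supporting prefix-sum sampling.
struct Fenwick {
    int n;
    std::vector<double> tree;
    std::vector<double> w;
    void init(int size) {
        n = size;
        tree.assign(n + 1, 0.0);
        w.assign(n, 0.0);
    }
    void set(int i, double val) {
        double d = val - w[i];
        if (d == 0.0) return;
        w[i] = val;
        for (int j = i + 1; j <= n; j += j & (-j)) tree[j] += d;
    }
    double total() const {
        double s = 0.0;
        for (int j = n; j > 0; j -= j & (-j)) s += tree[j];
        return s;
    }
    // smallest index with prefix sum > u (u in [0, total))
    int find(double u) const {
        int pos = 0;
        int logn = 1;
        while ((1 << logn) <= n) ++logn;
        for (int k = logn; k >= 0; --k) {
            int nxt = pos + (1 << k);
            if (nxt <= n && tree[nxt] <= u) {
                u -= tree[nxt];
                pos = nxt;
            }
        }
        if (pos >= n) pos = n - 1;   // guard against fp drift
        while (pos > 0 && w[pos] <= 0.0) --pos;
        return pos;
    }
};

struct Frag {
    int chain;
    int lo, hi;     // monomer span, inclusive, chain-local coordinates
    int cbh;        // attachment index or -1
    bool alive;
};

struct Attach {
    int frag;
    int chain;
    int dir;        // +1: working end at frag lo, eating rightward
    int zpos;       // chain-local index of current terminal monomer
    double deadline;
    double factor;  // crystallinity factor of the next bond to cut
    bool active;
};

struct Engine {
    // ---- geometry ----
    int nSite, slots;
    std::vector<double> sx, sy;                    // site coordinates, nm
    std::vector<std::array<int, 4>> nbr;           // -1 = open medium
    std::vector<std::vector<int>> gridChain;       // site x slot -> chain | -1
    std::vector<std::vector<double>> siteD2;       // pairwise lateral dist^2

    // ---- chains ----
    int nChain, nBond, nMono;
    std::vector<int> cSite, cStart, cLen, cKind;   // kind: 0 cel, 1 hemi, 2 lig
    std::vector<int> bondOff, monOff;
    std::vector<char> cryst;                       // per bond
    std::vector<char> cover;                       // per monomer (lignin)
    std::vector<char> intact;                      // per bond
    std::vector<char> present;                     // per monomer
    bool structured;
    double rCell, rHemi;

    // ---- dynamic state ----
    std::vector<Frag> frags;
    std::vector<int> fragOfBond;
    std::vector<Attach> atts;
    std::vector<int> activeAtt;
    std::priority_queue<std::pair<double, int>,
                        std::vector<std::pair<double, int>>,
                        std::greater<std::pair<double, int>>> detachQ;
    Fenwick fenEG, fenXYL, fenFrag;
    std::vector<char> acc;                         // per-bond accessibility
    std::vector<std::vector<short>> ster;          // site x slot blocked count
    int freeEG, freeCBH, freeBGL, freeXYL;
    int boundEG, boundCBH, boundBGL, boundXYL;
    long pool;
    long nCellobiose, nGlucose, nXylose;
    long initGlc, initXyl;
    double clock_;
    long events;

    // ---- kinetics ----
    double kEG, kXYL, kBGL, kAtt, kCBH, tCBH, sigmaT, Rcbh, kBind;
    double ligMean, ligSd;
    int cntEG, cntCBH, cntBGL, cntXYL;

    // ------------------------------------------------------------------
    bool blocking(int s, int z) const {
        int c2 = gridChain[s][z];
        if (c2 < 0) return false;
        int m = z - cStart[c2];
        if (cKind[c2] == 2) return cover[monOff[c2] + m] != 0;
        return present[monOff[c2] + m] != 0;
    }

    bool computeAccess(int c, int i) const {
        if (!structured) return true;
        int b = bondOff[c] + i;
        if (i > 0 && !intact[b - 1]) return true;
        if (i < cLen[c] - 2 && !intact[b + 1]) return true;
        int a = cStart[c] + i;
        int s = cSite[c];
        for (int d = 0; d < 4; ++d) {
            int n = nbr[s][d];
            if (n < 0) return true;
            if (!blocking(n, a) && !blocking(n, a + 1)) return true;
        }
        return false;
    }

    bool sterBlocked(int c, int i) const {
        if (!structured) return false;
        int a = cStart[c] + i;
        int s = cSite[c];
        return ster[s][a] > 0 || ster[s][a + 1] > 0;
    }

    int fragEndWeight(const Frag &f) const {
        if (!f.alive || cKind[f.chain] != 0 || f.cbh >= 0) return 0;
        if (f.hi - f.lo + 1 < 2) return 0;
        int w = 0;
        if (acc[bondOff[f.chain] + f.lo]) ++w;
        if (f.hi - 1 > f.lo && acc[bondOff[f.chain] + f.hi - 1]) ++w;
        else if (f.hi - 1 == f.lo) w = w > 0 ? 1 : 0;  // single bond, one end
        return w;
    }

    void refreshFrag(int fid) {
        fenFrag.set(fid, (double)fragEndWeight(frags[fid]));
    }

    // recompute a bond's weights from scratch
    void setWeight(int c, int i) {
        int b = bondOff[c] + i;
        bool ok = intact[b] != 0;
        bool newAcc = ok && computeAccess(c, i);
        bool accChanged = (acc[b] != 0) != newAcc;
        acc[b] = newAcc ? 1 : 0;
        double wEG = 0.0, wXYL = 0.0;
        if (ok && newAcc && !sterBlocked(c, i)) {
            double f = cryst[b] ? (cKind[c] == 0 ? rCell : rHemi) : 1.0;
            if (cKind[c] == 0) {
                const Frag &fr = frags[fragOfBond[b]];
                if (i - fr.lo >= 2 && (fr.hi - 1) - i >= 2) wEG = f;
            } else if (cKind[c] == 1) {
                wXYL = f;
            }
        }
        fenEG.set(b, wEG);
        fenXYL.set(b, wXYL);
        if (accChanged) {
            int fid = fragOfBond[b];
            const Frag &fr = frags[fid];
            if (fr.alive && (i == fr.lo || i == fr.hi - 1)) refreshFrag(fid);
        }
    }

    void updateAroundSlot(int s, int z) {
        if (!structured) return;
        for (int d = 0; d < 4; ++d) {
            int n = nbr[s][d];
            if (n < 0) continue;
            int c2 = gridChain[n][z];
            if (c2 < 0) continue;
            int m = z - cStart[c2];
            if (m - 1 >= 0 && m - 1 <= cLen[c2] - 2) setWeight(c2, m - 1);
            if (m <= cLen[c2] - 2) setWeight(c2, m);
        }
    }

    void releaseMonomer(int c, int m) {
        present[monOff[c] + m] = 0;
        int z = cStart[c] + m;
        updateAroundSlot(cSite[c], z);
    }

    // ---- steric zone ----
    void zoneApply(int s0, double z0, int delta) {
        if (!structured) return;
        double R2 = 4.0 * Rcbh * Rcbh;
        for (int s = 0; s < nSite; ++s) {
            double d2 = siteD2[s0][s];
            if (d2 > R2) continue;
            double w = std::sqrt(R2 - d2);
            int lo = std::max(0, (int)std::ceil(z0 - w));
            int hi = std::min(slots - 1, (int)std::floor(z0 + w));
            for (int z = lo; z <= hi; ++z) {
                short before = ster[s][z];
                ster[s][z] = (short)(before + delta);
                if ((before > 0) == (ster[s][z] > 0)) continue;
                int c2 = gridChain[s][z];
                if (c2 < 0) continue;
                int m = z - cStart[c2];
                if (m - 1 >= 0 && m - 1 <= cLen[c2] - 2) setWeight(c2, m - 1);
                if (m <= cLen[c2] - 2) setWeight(c2, m);
            }
        }
    }

    void zoneShift(int s0, double zOld, double zNew) {
        // remove/add only the symmetric difference of the two axial intervals
        if (!structured) return;
        double R2 = 4.0 * Rcbh * Rcbh;
        for (int s = 0; s < nSite; ++s) {
            double d2 = siteD2[s0][s];
            if (d2 > R2) continue;
            double w = std::sqrt(R2 - d2);
            int lo1 = std::max(0, (int)std::ceil(zOld - w));
            int hi1 = std::min(slots - 1, (int)std::floor(zOld + w));
            int lo2 = std::max(0, (int)std::ceil(zNew - w));
            int hi2 = std::min(slots - 1, (int)std::floor(zNew + w));
            for (int z = lo1; z <= hi1; ++z) {
                if (z >= lo2 && z <= hi2) continue;
                touchSter(s, z, -1);
            }
            for (int z = lo2; z <= hi2; ++z) {
                if (z >= lo1 && z <= hi1) continue;
                touchSter(s, z, +1);
            }
        }
    }

    void touchSter(int s, int z, int delta) {
        short before = ster[s][z];
        ster[s][z] = (short)(before + delta);
        if ((before > 0) == (ster[s][z] > 0)) return;
        int c2 = gridChain[s][z];
        if (c2 < 0) return;
        int m = z - cStart[c2];
        if (m - 1 >= 0 && m - 1 <= cLen[c2] - 2) setWeight(c2, m - 1);
        if (m <= cLen[c2] - 2) setWeight(c2, m);
    }

    // ---- fragment surgery ----
    int newFrag(int chain, int lo, int hi) {
        Frag f;
        f.chain = chain; f.lo = lo; f.hi = hi; f.cbh = -1; f.alive = true;
        frags.push_back(f);
        return (int)frags.size() - 1;
    }

    // digest bond i of chain c, splitting its fragment; returns (leftId, rightId)
    std::pair<int, int> cutBond(int c, int i) {
        int b = bondOff[c] + i;
        intact[b] = 0;
        int fid = frags[fragOfBond[b]].alive ? fragOfBond[b] : fragOfBond[b];
        Frag &f = frags[fid];
        int lo = f.lo, hi = f.hi, cbh = f.cbh;
        int leftLen = i - lo + 1, rightLen = hi - i;
        int leftId, rightId;
        if (leftLen <= rightLen) {
            // relabel the left side
            leftId = newFrag(c, lo, i);
            frags[fid].lo = i + 1;
            rightId = fid;
            for (int j = lo; j <= i - 1; ++j) fragOfBond[bondOff[c] + j] = leftId;
        } else {
            rightId = newFrag(c, i + 1, hi);
            frags[fid].hi = i;
            leftId = fid;
            for (int j = i + 1; j <= hi - 1; ++j) fragOfBond[bondOff[c] + j] = rightId;
        }
        fragOfBond[b] = leftId;  // the cut bond borders the left fragment
        // reassign an attached CBH to the side that holds it
        if (cbh >= 0) {
            Attach &a = atts[cbh];
            int holder = (a.zpos <= i) ? leftId : rightId;
            int other = (holder == leftId) ? rightId : leftId;
            frags[holder].cbh = cbh;
            frags[other].cbh = -1;
            a.frag = holder;
        }
        // refresh weights near the new ends (accessibility + EG end rule)
        for (int j = i - 2; j <= i + 2; ++j)
            if (j >= 0 && j <= cLen[c] - 2) setWeight(c, j);
        refreshFrag(leftId);
        refreshFrag(rightId);
        return std::make_pair(leftId, rightId);
    }

    void killFrag(int fid) {
        frags[fid].alive = false;
        fenFrag.set(fid, 0.0);
    }

    // release a whole fragment of length 1 (monomer becomes free sugar)
    void releaseSingleton(int fid) {
        Frag &f = frags[fid];
        int c = f.chain;
        if (cKind[c] == 0) ++nGlucose; else ++nXylose;
        releaseMonomer(c, f.lo);
        killFrag(fid);
    }

    // ---- CBH mechanics ----
    double stepFactor(const Attach &a) const {
        const Frag &f = frags[a.frag];
        int len = f.hi - f.lo + 1;
        int bond;
        if (len >= 3) bond = (a.dir > 0) ? f.lo + 1 : f.hi - 2;
        else bond = f.lo;   // lone dimer: its internal bond
        return cryst[bondOff[f.chain] + bond] ? rCell : 1.0;
    }

    void doAttach(int fid, int endSide /*0 = lo, 1 = hi*/) {
        Frag &f = frags[fid];
        Attach a;
        a.frag = fid;
        a.chain = f.chain;
        a.dir = endSide == 0 ? +1 : -1;
        a.zpos = endSide == 0 ? f.lo : f.hi;
        double t = 0.0;
        if (sigmaT <= 0.0) t = tCBH;
        else { do { t = R::rnorm(tCBH, sigmaT); } while (t <= 0.0); }
        a.deadline = clock_ + t;
        a.active = true;
        atts.push_back(a);
        int id = (int)atts.size() - 1;
        atts[id].factor = 0.0;
        f.cbh = id;
        --freeCBH;
        activeAtt.push_back(id);
        refreshFrag(fid);
        zoneApply(cSite[f.chain], cStart[f.chain] + a.zpos, +1);
        atts[id].factor = stepFactor(atts[id]);
    }

    void doDetach(int id) {
        Attach &a = atts[id];
        if (!a.active) return;
        a.active = false;
        ++freeCBH;
        zoneApply(cSite[a.chain], cStart[a.chain] + a.zpos, -1);
        activeAtt.erase(std::find(activeAtt.begin(), activeAtt.end(), id));
        if (frags[a.frag].alive && frags[a.frag].cbh == id) {
            frags[a.frag].cbh = -1;
            refreshFrag(a.frag);
        }
    }

    void doStep(int id) {
        Attach &a = atts[id];
        Frag &f = frags[a.frag];
        int c = f.chain;
        int len = f.hi - f.lo + 1;
        if (len == 2) {
            // lift the whole dimer off as cellobiose
            int b = bondOff[c] + f.lo;
            intact[b] = 0;
            setWeight(c, f.lo);
            ++nCellobiose;
            releaseMonomer(c, f.lo);
            releaseMonomer(c, f.hi);
            killFrag(a.frag);
            doDetach(id);
            return;
        }
        int m1, m2, cutAt, newEnd;
        if (a.dir > 0) { m1 = f.lo; m2 = f.lo + 1; cutAt = f.lo + 1; newEnd = f.lo + 2; }
        else           { m1 = f.hi; m2 = f.hi - 1; cutAt = f.hi - 2; newEnd = f.hi - 2; }
        int b = bondOff[c] + cutAt;
        intact[b] = 0;
        // terminal bond inside the released cellobiose also leaves the lattice
        int innerBond = (a.dir > 0) ? f.lo : f.hi - 1;
        intact[bondOff[c] + innerBond] = 0;
        ++nCellobiose;
        if (a.dir > 0) f.lo += 2; else f.hi -= 2;
        releaseMonomer(c, m1);
        releaseMonomer(c, m2);
        for (int j = cutAt - 2; j <= cutAt + 2; ++j)
            if (j >= 0 && j <= cLen[c] - 2) setWeight(c, j);
        if (f.hi == f.lo) {
            // single monomer remains: released as free glucose, CBH detaches
            ++nGlucose;
            releaseMonomer(c, f.lo);
            killFrag(a.frag);
            doDetach(id);
            return;
        }
        double zOld = cStart[c] + a.zpos;
        a.zpos = newEnd;
        zoneShift(cSite[c], zOld, cStart[c] + a.zpos);
        a.factor = stepFactor(a);
        refreshFrag(a.frag);
    }

    // ---- events ----
    void doEG() {
        int b = fenEG.find(R::unif_rand() * fenEG.total());
        int c = chainOfBond(b);
        cutBond(c, b - bondOff[c]);
    }

    void doXYL() {
        int b = fenXYL.find(R::unif_rand() * fenXYL.total());
        int c = chainOfBond(b);
        std::pair<int, int> lr = cutBond(c, b - bondOff[c]);
        if (frags[lr.first].alive && frags[lr.first].hi == frags[lr.first].lo)
            releaseSingleton(lr.first);
        if (frags[lr.second].alive && frags[lr.second].hi == frags[lr.second].lo)
            releaseSingleton(lr.second);
    }

    void doBGL() {
        --nCellobiose;
        nGlucose += 2;
    }

    void doAttachEvent() {
        double u = R::unif_rand() * fenFrag.total();
        int fid = fenFrag.find(u);
        Frag &f = frags[fid];
        int b0 = bondOff[f.chain];
        bool loOK = acc[b0 + f.lo] != 0;
        bool hiOK = (f.hi - 1 != f.lo) && acc[b0 + f.hi - 1] != 0;
        int side;
        if (loOK && hiOK) side = (R::unif_rand() < 0.5) ? 0 : 1;
        else side = loOK ? 0 : 1;
        doAttach(fid, side);
    }

    void doLigninBind() {
        double totF = freeEG + freeCBH + freeBGL + freeXYL;
        double u = R::unif_rand() * totF;
        if (u < freeEG) { --freeEG; ++boundEG; }
        else if (u < freeEG + freeCBH) { --freeCBH; ++boundCBH; }
        else if (u < freeEG + freeCBH + freeBGL) { --freeBGL; ++boundBGL; }
        else { --freeXYL; ++boundXYL; }
        long consumed;
        if (ligSd <= 0.0) consumed = (long)std::lround(ligMean);
        else consumed = (long)std::lround(R::rnorm(ligMean, ligSd));
        if (consumed < 1) consumed = 1;
        if (consumed > pool) consumed = pool;
        pool -= consumed;
    }

    int chainOfBond(int b) const {
        int lo = 0, hi = nChain - 1;
        while (lo < hi) {
            int mid = (lo + hi + 1) / 2;
            if (bondOff[mid] <= b) lo = mid; else hi = mid - 1;
        }
        return lo;
    }

    void checkConservation() const {
        long sumCel = 0, sumXyl = 0;
        for (int c = 0; c < nChain; ++c) {
            if (cKind[c] == 2) continue;
            long s = 0;
            for (int m = 0; m < cLen[c]; ++m) s += present[monOff[c] + m];
            if (cKind[c] == 0) sumCel += s; else sumXyl += s;
        }
        if (sumCel + 2 * nCellobiose + nGlucose != initGlc)
            stop("glucose conservation violated");
        if (sumXyl + nXylose != initXyl)
            stop("xylose conservation violated");
        int attached = (int)activeAtt.size();
        if (freeEG + boundEG != cntEG || freeBGL + boundBGL != cntBGL ||
            freeXYL + boundXYL != cntXYL ||
            freeCBH + boundCBH + attached != cntCBH)
            stop("enzyme headcount violated");
    }
};

} // namespace

// [[Rcpp::export]]
List cpp_run_engine(List fib, List kin, List cfg) {
    Engine E;

    // ---- geometry ----
    NumericVector sx = fib["site_x"], sy = fib["site_y"];
    IntegerMatrix nbrM = fib["nbr"];               // nSite x 4, 0-based, -1 none
    E.nSite = sx.size();
    E.slots = as<int>(fib["slots"]);
    E.sx.assign(sx.begin(), sx.end());
    E.sy.assign(sy.begin(), sy.end());
    E.nbr.resize(E.nSite);
    for (int s = 0; s < E.nSite; ++s)
        for (int d = 0; d < 4; ++d) E.nbr[s][d] = nbrM(s, d);
    E.siteD2.assign(E.nSite, std::vector<double>(E.nSite, 0.0));
    for (int i = 0; i < E.nSite; ++i)
        for (int j = 0; j < E.nSite; ++j) {
            double dx = E.sx[i] - E.sx[j], dy = E.sy[i] - E.sy[j];
            E.siteD2[i][j] = dx * dx + dy * dy;
        }

    // ---- chains ----
    IntegerVector cs = fib["chain_site"], cst = fib["chain_start"],
                  cl = fib["chain_len"], ck = fib["chain_kind"];
    E.nChain = cs.size();
    E.cSite.assign(cs.begin(), cs.end());
    E.cStart.assign(cst.begin(), cst.end());
    E.cLen.assign(cl.begin(), cl.end());
    E.cKind.assign(ck.begin(), ck.end());
    E.bondOff.resize(E.nChain);
    E.monOff.resize(E.nChain);
    int bOff = 0, mOff = 0;
    for (int c = 0; c < E.nChain; ++c) {
        E.bondOff[c] = bOff; E.monOff[c] = mOff;
        bOff += std::max(0, E.cLen[c] - 1);
        mOff += E.cLen[c];
    }
    E.nBond = bOff; E.nMono = mOff;
    LogicalVector cr = fib["cryst"], cv = fib["cover"];
    E.cryst.assign(E.nBond, 0);
    for (int i = 0; i < E.nBond; ++i) E.cryst[i] = cr[i] ? 1 : 0;
    E.cover.assign(E.nMono, 0);
    for (int i = 0; i < E.nMono; ++i) E.cover[i] = cv[i] ? 1 : 0;
    E.structured = as<bool>(fib["structured"]);
    E.rCell = as<double>(fib["r_ca_cellulose"]);
    E.rHemi = as<double>(fib["r_ca_hemicellulose"]);

    E.gridChain.assign(E.nSite, std::vector<int>(E.slots, -1));
    for (int c = 0; c < E.nChain; ++c)
        for (int m = 0; m < E.cLen[c]; ++m) {
            int s = E.cSite[c], z = E.cStart[c] + m;
            if (E.gridChain[s][z] >= 0) stop("overlapping chains on lattice");
            E.gridChain[s][z] = c;
        }

    // ---- kinetics ----
    IntegerVector counts = kin["counts"];
    E.cntEG = counts[0]; E.cntCBH = counts[1];
    E.cntBGL = counts[2]; E.cntXYL = counts[3];
    E.freeEG = E.cntEG; E.freeCBH = E.cntCBH;
    E.freeBGL = E.cntBGL; E.freeXYL = E.cntXYL;
    E.boundEG = E.boundCBH = E.boundBGL = E.boundXYL = 0;
    E.kEG = as<double>(kin["k_EG"]);
    E.kXYL = as<double>(kin["k_XYL"]);
    E.kBGL = as<double>(kin["k_BGL"]);
    E.kAtt = as<double>(kin["k_CBH_attach"]);
    E.kCBH = as<double>(kin["k_CBH"]);
    E.tCBH = as<double>(kin["t_CBH"]);
    E.sigmaT = as<double>(kin["sigma_t"]);
    E.Rcbh = as<double>(kin["R_CBH"]);
    E.kBind = as<double>(kin["k_bind"]);
    E.ligMean = as<double>(kin["N_lignols_bound"]);
    E.ligSd = as<double>(kin["sigma_lignols"]);

    // ---- initial state ----
    E.intact.assign(E.nBond, 1);
    E.present.assign(E.nMono, 1);
    E.acc.assign(E.nBond, 0);
    E.ster.assign(E.nSite, std::vector<short>(E.slots, 0));
    E.fragOfBond.assign(E.nBond, -1);
    E.frags.reserve(E.nChain + E.nBond + 4);
    E.fenFrag.init(E.nChain + E.nBond + 4);
    E.fenEG.init(std::max(1, E.nBond));
    E.fenXYL.init(std::max(1, E.nBond));
    E.initGlc = 0; E.initXyl = 0; E.pool = 0;
    for (int c = 0; c < E.nChain; ++c) {
        if (E.cKind[c] == 0) E.initGlc += E.cLen[c];
        else if (E.cKind[c] == 1) E.initXyl += E.cLen[c];
        else E.pool += E.cLen[c];
        int fid = E.newFrag(c, 0, E.cLen[c] - 1);
        for (int j = 0; j <= E.cLen[c] - 2; ++j)
            E.fragOfBond[E.bondOff[c] + j] = fid;
    }
    for (int c = 0; c < E.nChain; ++c)
        for (int j = 0; j <= E.cLen[c] - 2; ++j) E.setWeight(c, j);
    for (size_t f = 0; f < E.frags.size(); ++f) E.refreshFrag((int)f);
    E.nCellobiose = E.nGlucose = E.nXylose = 0;
    E.clock_ = 0.0;
    E.events = 0;

    // ---- run config ----
    double tEnd = as<double>(cfg["t_end"]);
    double maxEvents = as<double>(cfg["max_events"]);
    double recInt = as<double>(cfg["record_interval"]);
    bool recordDP = as<bool>(cfg["record_dp"]);
    int dpMax = as<int>(cfg["dp_max"]);
    bool returnState = as<bool>(cfg["return_state"]);
    bool debug = as<bool>(cfg["debug"]);

    std::vector<double> recT, recGlc, recXyl;
    std::vector<long> recNG, recNC, recNX;
    std::vector<std::vector<double>> recDP;

    auto snapshot = [&](double t) {
        recT.push_back(t);
        recGlc.push_back(E.initGlc > 0 ? 100.0 * E.nGlucose / E.initGlc : 0.0);
        recXyl.push_back(E.initXyl > 0 ? 100.0 * E.nXylose / E.initXyl : 0.0);
        recNG.push_back(E.nGlucose);
        recNC.push_back(E.nCellobiose);
        recNX.push_back(E.nXylose);
        if (recordDP) {
            std::vector<double> row(dpMax, 0.0);
            for (size_t f = 0; f < E.frags.size(); ++f) {
                const Frag &fr = E.frags[f];
                if (!fr.alive || E.cKind[fr.chain] != 0) continue;
                int len = fr.hi - fr.lo + 1;
                int bin = std::min(len, dpMax);
                row[bin - 1] += (double)len;
            }
            if (dpMax >= 2) row[1] += 2.0 * E.nCellobiose;
            row[0] += (double)E.nGlucose;
            for (int i = 0; i < dpMax; ++i) row[i] /= (double)E.initGlc;
            recDP.push_back(row);
        }
        if (debug) E.checkConservation();
    };

    double nextRec = 0.0;
    std::string stopReason = "t_end";

    RNGScope rngScope;
    bool done = false;
    while (!done) {
        if (E.events >= (long)maxEvents) { stopReason = "max_events"; break; }
        // totals
        double aEG = E.kEG * E.freeEG * (E.cntEG > 0 ? E.fenEG.total() : 0.0);
        double aXYL = E.kXYL * E.freeXYL * (E.cntXYL > 0 ? E.fenXYL.total() : 0.0);
        double aBGL = E.kBGL * E.freeBGL * (double)E.nCellobiose;
        double aATT = E.kAtt * E.freeCBH * E.fenFrag.total();
        double aSTEP = 0.0;
        for (size_t k = 0; k < E.activeAtt.size(); ++k)
            aSTEP += E.kCBH * E.atts[E.activeAtt[k]].factor;
        int totFree = E.freeEG + E.freeCBH + E.freeBGL + E.freeXYL;
        double aLIG = (E.pool > 0 && totFree > 0) ? E.kBind * totFree : 0.0;
        double tot = aEG + aXYL + aBGL + aATT + aSTEP + aLIG;
        if (aEG < 0) aEG = 0;  // fp drift guard
        double tNext = (tot > 0) ? E.clock_ + R::exp_rand() / tot : INF;
        double tDet = INF;
        int detId = -1;
        while (!E.detachQ.empty()) {
            std::pair<double, int> top = E.detachQ.top();
            if (!E.atts[top.second].active) { E.detachQ.pop(); continue; }
            tDet = top.first; detId = top.second;
            break;
        }
        double tEvent = std::min(tNext, tDet);
        if (tEvent == INF) { stopReason = "exhausted"; break; }
        // flush records up to the event time
        while (nextRec <= std::min(tEvent, tEnd) + 1e-12) {
            snapshot(nextRec);
            nextRec += recInt;
        }
        if (tEvent > tEnd) { E.clock_ = tEnd; stopReason = "t_end"; break; }
        E.clock_ = tEvent;
        if (tDet <= tNext) {
            E.detachQ.pop();
            E.doDetach(detId);
        } else {
            double u = R::unif_rand() * tot;
            if (u < aEG) E.doEG();
            else if (u < aEG + aXYL) E.doXYL();
            else if (u < aEG + aXYL + aBGL) E.doBGL();
            else if (u < aEG + aXYL + aBGL + aATT) {
                E.doAttachEvent();
                int id = (int)E.atts.size() - 1;
                E.detachQ.push(std::make_pair(E.atts[id].deadline, id));
            } else if (u < aEG + aXYL + aBGL + aATT + aSTEP) {
                double v = u - (aEG + aXYL + aBGL + aATT);
                int chosen = -1;
                for (size_t k = 0; k < E.activeAtt.size(); ++k) {
                    double w = E.kCBH * E.atts[E.activeAtt[k]].factor;
                    if (v < w) { chosen = E.activeAtt[k]; break; }
                    v -= w;
                }
                if (chosen < 0) chosen = E.activeAtt.back();
                E.doStep(chosen);
            } else {
                E.doLigninBind();
            }
        }
        ++E.events;
        if (debug) E.checkConservation();
    }
    // flush the remaining grid (state is frozen after the stop); with an
    // event-count stopping rule and no finite horizon, close at the clock
    double flushEnd = std::isfinite(tEnd) ? tEnd : E.clock_;
    while (nextRec <= flushEnd + 1e-12) {
        snapshot(nextRec);
        nextRec += recInt;
    }
    if (recT.empty() || recT.back() < E.clock_) snapshot(E.clock_);

    List out = List::create(
        _["times"] = wrap(recT),
        _["glucan_pct"] = wrap(recGlc),
        _["xylan_pct"] = wrap(recXyl),
        _["glucose"] = wrap(std::vector<double>(recNG.begin(), recNG.end())),
        _["cellobiose"] = wrap(std::vector<double>(recNC.begin(), recNC.end())),
        _["xylose"] = wrap(std::vector<double>(recNX.begin(), recNX.end())),
        _["stop_reason"] = stopReason,
        _["event_count"] = (double)E.events,
        _["clock"] = E.clock_,
        _["init_glc"] = (double)E.initGlc,
        _["init_xyl"] = (double)E.initXyl,
        _["pool"] = (double)E.pool,
        _["free_counts"] = IntegerVector::create(E.freeEG, E.freeCBH, E.freeBGL, E.freeXYL),
        _["bound_counts"] = IntegerVector::create(E.boundEG, E.boundCBH, E.boundBGL, E.boundXYL));

    if (recordDP) {
        NumericMatrix dp((int)recDP.size(), dpMax);
        for (size_t i = 0; i < recDP.size(); ++i)
            for (int j = 0; j < dpMax; ++j) dp((int)i, j) = recDP[i][j];
        out["dp"] = dp;
    }

    if (returnState) {
        int nf = (int)E.frags.size();
        IntegerVector fc(nf), flo(nf), fhi(nf), fcbh(nf);
        LogicalVector fal(nf);
        for (int i = 0; i < nf; ++i) {
            fc[i] = E.frags[i].chain; flo[i] = E.frags[i].lo;
            fhi[i] = E.frags[i].hi; fcbh[i] = E.frags[i].cbh;
            fal[i] = E.frags[i].alive;
        }
        int na = (int)E.atts.size();
        IntegerVector ac(na), af(na), ad(na), az(na);
        NumericVector adl(na);
        LogicalVector aac(na);
        for (int i = 0; i < na; ++i) {
            ac[i] = E.atts[i].chain; af[i] = E.atts[i].frag;
            ad[i] = E.atts[i].dir; az[i] = E.atts[i].zpos;
            adl[i] = E.atts[i].deadline; aac[i] = E.atts[i].active;
        }
        NumericVector wEG(E.nBond), wXYL(E.nBond);
        LogicalVector accV(E.nBond), sterV(E.nBond);
        for (int c = 0; c < E.nChain; ++c)
            for (int j = 0; j <= E.cLen[c] - 2; ++j) {
                int b = E.bondOff[c] + j;
                wEG[b] = E.fenEG.w[b];
                wXYL[b] = E.fenXYL.w[b];
                accV[b] = E.acc[b] != 0;
                sterV[b] = E.sterBlocked(c, j);
            }
        NumericVector fragW(nf);
        for (int i = 0; i < nf; ++i) fragW[i] = E.fenFrag.w[i];
        out["state"] = List::create(
            _["intact"] = LogicalVector(E.intact.begin(), E.intact.end()),
            _["present"] = LogicalVector(E.present.begin(), E.present.end()),
            _["frags"] = DataFrame::create(
                _["chain"] = fc, _["lo"] = flo, _["hi"] = fhi,
                _["cbh"] = fcbh, _["alive"] = fal),
            _["attachments"] = DataFrame::create(
                _["chain"] = ac, _["frag"] = af, _["dir"] = ad,
                _["zpos"] = az, _["deadline"] = adl, _["active"] = aac),
            _["w_eg"] = wEG, _["w_xyl"] = wXYL,
            _["accessible"] = accV, _["steric_blocked"] = sterV,
            _["frag_weight"] = fragW,
            _["sum_eg"] = E.fenEG.total(), _["sum_xyl"] = E.fenXYL.total(),
            _["sum_frag"] = E.fenFrag.total());
    }
    return out;
}
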