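#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Integrated EHH (iHH) for every requested core variant and both core
// alleles, over physical distance (bp).
//
// For one core allele, carriers are grouped by identity of the haplotype
// stretch from the core through the current marker; EHH at that marker is
// sum_g C(n_g,2) / C(n_c,2). Scanning a flank stops when EHH drops below
// the decay floor (area closed by linear interpolation to the crossing),
// when the chromosome ends first (reason "edge"), or when an inter-marker
// gap exceeds maxGap (reason "gap"). Only a flank closed at the floor
// yields a valid area unless integrateEdge is set.
//
// Reason codes per allele: 0 = ok, 1 = <2 carriers, 2 = edge, 3 = gap.

static const int OK = 0, FEW_CARRIERS = 1, EDGE = 2, GAP = 3;

// One flank scan. dir = -1 (left) or +1 (right); lim = last index of the
// chromosome in that direction (inclusive). Returns area; sets reason.
static double scan_flank(const IntegerMatrix& alleles,
                         const IntegerVector& pos,
                         const std::vector<int>& carriers,
                         int core, int dir, int lim,
                         double floorv, double maxGap,
                         int& reason) {
    const int nc = (int)carriers.size();
    const double totPairs = (double)nc * (nc - 1) / 2.0;
    std::vector<int> gid(nc, 0);
    int nGroups = 1;
    double prevPos = pos[core], prevEhh = 1.0, area = 0.0;
    std::vector<int> remap;

    for (int m = core + dir; dir > 0 ? m <= lim : m >= lim; m += dir) {
        double gap = std::abs((double)pos[m] - prevPos);
        if (gap > maxGap) { reason = GAP; return area; }
        // refine groups by allele at m
        remap.assign(2 * nGroups, -1);
        int nNew = 0;
        for (int i = 0; i < nc; ++i) {
            int key = gid[i] * 2 + alleles(carriers[i], m);
            if (remap[key] < 0) remap[key] = nNew++;
            gid[i] = remap[key];
        }
        std::vector<int> cnt(nNew, 0);
        for (int i = 0; i < nc; ++i) cnt[gid[i]]++;
        double pairs = 0.0;
        for (int g = 0; g < nNew; ++g)
            pairs += (double)cnt[g] * (cnt[g] - 1) / 2.0;
        double ehh = pairs / totPairs;
        nGroups = nNew;
        if (ehh < floorv) {
            // linear interpolation to the floor crossing
            double dx = gap * (prevEhh - floorv) / (prevEhh - ehh);
            area += 0.5 * (prevEhh + floorv) * dx;
            reason = OK;
            return area;
        }
        area += 0.5 * (prevEhh + ehh) * gap;
        prevEhh = ehh;
        prevPos = pos[m];
    }
    reason = EDGE; // chromosome end reached with EHH still at/above floor
    return area;
}

// [[Rcpp::export]]
DataFrame ihh_scan_cpp(const IntegerMatrix& alleles,
                       const IntegerVector& pos,
                       const IntegerVector& chromId,
                       const LogicalVector& doCore,
                       double decayFloor, double maxGap,
                       bool integrateEdge) {
    const int nHap = alleles.nrow(), nVar = alleles.ncol();
    if (pos.size() != nVar || chromId.size() != nVar || doCore.size() != nVar)
        stop("inconsistent scan inputs");

    // chromosome index ranges (chromId must be sorted, contiguous)
    std::vector<int> chromFirst(nVar), chromLast(nVar);
    for (int j = 0; j < nVar; ++j) {
        chromFirst[j] = (j > 0 && chromId[j] == chromId[j - 1])
            ? chromFirst[j - 1] : j;
    }
    for (int j = nVar - 1; j >= 0; --j) {
        chromLast[j] = (j < nVar - 1 && chromId[j] == chromId[j + 1])
            ? chromLast[j + 1] : j;
    }

    NumericVector ihhA(nVar, NA_REAL), ihhD(nVar, NA_REAL);
    IntegerVector reasonA(nVar, NA_INTEGER), reasonD(nVar, NA_INTEGER);
    std::vector<int> car0, car1;
    car0.reserve(nHap); car1.reserve(nHap);

    for (int j = 0; j < nVar; ++j) {
        if (!doCore[j]) continue;
        car0.clear(); car1.clear();
        for (int i = 0; i < nHap; ++i)
            (alleles(i, j) == 1 ? car1 : car0).push_back(i);
        // allele 1 = derived, allele 0 = ancestral (panel must be polarized)
        const std::vector<int>* cars[2] = { &car0, &car1 };
        for (int a = 0; a < 2; ++a) {
            double ihh = NA_REAL;
            int reason = OK;
            if ((int)cars[a]->size() < 2) {
                reason = FEW_CARRIERS;
            } else {
                int rl = OK, rr = OK;
                double left = scan_flank(alleles, pos, *cars[a], j, -1,
                                         chromFirst[j], decayFloor, maxGap, rl);
                double right = scan_flank(alleles, pos, *cars[a], j, +1,
                                          chromLast[j], decayFloor, maxGap, rr);
                reason = std::max(rl, rr); // gap > edge > ok in severity order
                bool valid = (rl == OK || (integrateEdge && rl == EDGE)) &&
                             (rr == OK || (integrateEdge && rr == EDGE));
                if (valid) { ihh = left + right; reason = OK; }
            }
            if (a == 0) { ihhA[j] = ihh; reasonA[j] = reason; }
            else        { ihhD[j] = ihh; reasonD[j] = reason; }
        }
    }
    return DataFrame::create(_["ihh_a"] = ihhA, _["ihh_d"] = ihhD,
                             _["reason_a"] = reasonA, _["reason_d"] = reasonD);
}
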