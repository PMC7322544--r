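/* O'Hara-Rudy dynamic (ORd) human ventricular myocyte model, endocardial
 * parameterisation, with per-current conductance multipliers used both for
 * population-of-models variability and for Hill pore-block drug scaling.
 *
 * State vector (41 entries) and formulation follow the published ORd model
 * equations; conductance multipliers enter exactly once, on the maximal
 * conductance/permeability of the named current.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define N_STATE 41
#define N_PARMS 13

/* parms: 0..8  multipliers for INa, INaL, Ito, IKr, IKs, IK1, ICaL, INaCa, INaK
 *        9     stimulus current (uA/uF, negative = depolarising) currently on
 *        10    celltype (0 endo, 1 epi, 2 mid)
 *        11,12 reserved (extracellular [K]o override <=0 means default, spare)
 */
static double parms[N_PARMS];

void ord_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

/* indices into the state vector */
enum {
    iv = 0, inai, inass, iki, ikss, icai, icass, icansr, icajsr,
    im, ihf, ihs, ij, ihsp, ijp, imL, ihL, ihLp,
    ia, iiF, iiS, iap, iiFp, iiSp,
    id, iff_, ifs, ifcaf, ifcas, ijca, inca, iffp, ifcafp,
    ixrf, ixrs, ixs1, ixs2, ixk1, iJrelnp, iJrelp, iCaMKt
};

static void ord_deriv_core(double t, const double *y, double *ydot,
                           const double *p)
{
    /* physical constants and geometry */
    const double nao = 140.0, cao = 1.8, ko = 5.4;
    const double Rgas = 8314.0, T = 310.0, F = 96485.0;
    const double L = 0.01, rad = 0.0011;
    const double vcell = 1000.0 * 3.14 * rad * rad * L;
    const double Ageo = 2.0 * 3.14 * rad * rad + 2.0 * 3.14 * rad * L;
    const double Acap = 2.0 * Ageo;
    const double vmyo = 0.68 * vcell, vnsr = 0.0552 * vcell;
    const double vjsr = 0.0048 * vcell, vss = 0.02 * vcell;

    const double sNa = p[0], sNaL = p[1], sto = p[2], sKr = p[3], sKs = p[4];
    const double sK1 = p[5], sCaL = p[6], sNCX = p[7], sNaK = p[8];
    const double Ist = p[9];
    const int celltype = (int) p[10];

    double v = y[iv];
    double nai = y[inai], nass = y[inass], ki = y[iki], kss = y[ikss];
    double cai = y[icai], cass = y[icass], cansr = y[icansr], cajsr = y[icajsr];

    /* CaMK */
    const double KmCaMK = 0.15, aCaMK = 0.05, bCaMK = 0.00068;
    const double CaMKo = 0.05, KmCaM = 0.0015;
    double CaMKb = CaMKo * (1.0 - y[iCaMKt]) / (1.0 + KmCaM / cass);
    double CaMKa = CaMKb + y[iCaMKt];
    ydot[iCaMKt] = aCaMK * CaMKb * CaMKa - bCaMK * y[iCaMKt];

    /* reversal potentials */
    double ENa = (Rgas * T / F) * log(nao / nai);
    double EK  = (Rgas * T / F) * log(ko / ki);
    const double PKNa = 0.01833;
    double EKs = (Rgas * T / F) * log((ko + PKNa * nao) / (ki + PKNa * nai));
    double vffrt = v * F * F / (Rgas * T);
    double vfrt = v * F / (Rgas * T);

    /* INa (fast) */
    double mss = 1.0 / (1.0 + exp(-(v + 39.57) / 9.871));
    double tm = 1.0 / (6.765 * exp((v + 11.64) / 34.77) +
                       8.552 * exp(-(v + 77.42) / 5.955));
    ydot[im] = (mss - y[im]) / tm;
    double hss = 1.0 / (1.0 + exp((v + 82.90) / 6.086));
    double thf = 1.0 / (1.432e-5 * exp(-(v + 1.196) / 6.285) +
                        6.149 * exp((v + 0.5096) / 20.27));
    double ths = 1.0 / (0.009794 * exp(-(v + 17.95) / 28.05) +
                        0.3343 * exp((v + 5.730) / 56.66));
    const double Ahf = 0.99, Ahs = 0.01;
    ydot[ihf] = (hss - y[ihf]) / thf;
    ydot[ihs] = (hss - y[ihs]) / ths;
    double h = Ahf * y[ihf] + Ahs * y[ihs];
    double jss = hss;
    double tj = 2.038 + 1.0 / (0.02136 * exp(-(v + 100.6) / 8.281) +
                               0.3052 * exp((v + 0.9941) / 38.45));
    ydot[ij] = (jss - y[ij]) / tj;
    double hssp = 1.0 / (1.0 + exp((v + 89.1) / 6.086));
    double thsp = 3.0 * ths;
    ydot[ihsp] = (hssp - y[ihsp]) / thsp;
    double hp = Ahf * y[ihf] + Ahs * y[ihsp];
    double tjp = 1.46 * tj;
    ydot[ijp] = (jss - y[ijp]) / tjp;
    double GNa = 75.0 * sNa;
    double fINap = 1.0 / (1.0 + KmCaMK / CaMKa);
    double m3 = y[im] * y[im] * y[im];
    double INa = GNa * (v - ENa) * m3 *
        ((1.0 - fINap) * h * y[ij] + fINap * hp * y[ijp]);

    /* INaL */
    double mLss = 1.0 / (1.0 + exp(-(v + 42.85) / 5.264));
    double tmL = tm;
    ydot[imL] = (mLss - y[imL]) / tmL;
    double hLss = 1.0 / (1.0 + exp((v + 87.61) / 7.488));
    const double thL = 200.0;
    ydot[ihL] = (hLss - y[ihL]) / thL;
    double hLssp = 1.0 / (1.0 + exp((v + 93.81) / 7.488));
    double thLp = 3.0 * thL;
    ydot[ihLp] = (hLssp - y[ihLp]) / thLp;
    double GNaL = 0.0075 * sNaL;
    if (celltype == 1) GNaL *= 0.6;
    double fINaLp = fINap;
    double INaL = GNaL * (v - ENa) * y[imL] *
        ((1.0 - fINaLp) * y[ihL] + fINaLp * y[ihLp]);

    /* Ito */
    double ass = 1.0 / (1.0 + exp(-(v - 14.34) / 14.82));
    double ta = 1.0515 / (1.0 / (1.2089 * (1.0 + exp(-(v - 18.4099) / 29.3814))) +
                          3.5 / (1.0 + exp((v + 100.0) / 29.3814)));
    ydot[ia] = (ass - y[ia]) / ta;
    double iss = 1.0 / (1.0 + exp((v + 43.94) / 5.711));
    double delta_epi = 1.0;
    if (celltype == 1)
        delta_epi = 1.0 - 0.95 / (1.0 + exp((v + 70.0) / 5.0));
    double tiF = 4.562 + 1.0 / (0.3933 * exp(-(v + 100.0) / 100.0) +
                                0.08004 * exp((v + 50.0) / 16.59));
    double tiS = 23.62 + 1.0 / (0.001416 * exp(-(v + 96.52) / 59.05) +
                                1.780e-8 * exp((v + 114.1) / 8.079));
    tiF *= delta_epi; tiS *= delta_epi;
    double AiF = 1.0 / (1.0 + exp((v - 213.6) / 151.2));
    double AiS = 1.0 - AiF;
    ydot[iiF] = (iss - y[iiF]) / tiF;
    ydot[iiS] = (iss - y[iiS]) / tiS;
    double i_gate = AiF * y[iiF] + AiS * y[iiS];
    double assp = 1.0 / (1.0 + exp(-(v - 24.34) / 14.82));
    ydot[iap] = (assp - y[iap]) / ta;
    double dti_develop = 1.354 + 1.0e-4 /
        (exp((v - 167.4) / 15.89) + exp(-(v - 12.23) / 0.2154));
    double dti_recover = 1.0 - 0.5 / (1.0 + exp((v + 70.0) / 20.0));
    double tiFp = dti_develop * dti_recover * tiF;
    double tiSp = dti_develop * dti_recover * tiS;
    ydot[iiFp] = (iss - y[iiFp]) / tiFp;
    ydot[iiSp] = (iss - y[iiSp]) / tiSp;
    double ip = AiF * y[iiFp] + AiS * y[iiSp];
    double Gto = 0.02 * sto;
    if (celltype == 1 || celltype == 2) Gto *= 4.0;
    double fItop = fINap;
    double Ito = Gto * (v - EK) *
        ((1.0 - fItop) * y[ia] * i_gate + fItop * y[iap] * ip);

    /* ICaL / ICaNa / ICaK */
    double dss = 1.0 / (1.0 + exp(-(v + 3.940) / 4.230));
    double td = 0.6 + 1.0 / (exp(-0.05 * (v + 6.0)) + exp(0.09 * (v + 14.0)));
    ydot[id] = (dss - y[id]) / td;
    double fss = 1.0 / (1.0 + exp((v + 19.58) / 3.696));
    double tff = 7.0 + 1.0 / (0.0045 * exp(-(v + 20.0) / 10.0) +
                              0.0045 * exp((v + 20.0) / 10.0));
    double tfs = 1000.0 + 1.0 / (0.000035 * exp(-(v + 5.0) / 4.0) +
                                 0.000035 * exp((v + 5.0) / 6.0));
    const double Aff = 0.6, Afs = 0.4;
    ydot[iff_] = (fss - y[iff_]) / tff;
    ydot[ifs] = (fss - y[ifs]) / tfs;
    double f = Aff * y[iff_] + Afs * y[ifs];
    double fcass = fss;
    double tfcaf = 7.0 + 1.0 / (0.04 * exp(-(v - 4.0) / 7.0) +
                                0.04 * exp((v - 4.0) / 7.0));
    double tfcas = 100.0 + 1.0 / (0.00012 * exp(-v / 3.0) +
                                  0.00012 * exp(v / 7.0));
    double Afcaf = 0.3 + 0.6 / (1.0 + exp((v - 10.0) / 10.0));
    double Afcas = 1.0 - Afcaf;
    ydot[ifcaf] = (fcass - y[ifcaf]) / tfcaf;
    ydot[ifcas] = (fcass - y[ifcas]) / tfcas;
    double fca = Afcaf * y[ifcaf] + Afcas * y[ifcas];
    const double tjca = 75.0;
    ydot[ijca] = (fcass - y[ijca]) / tjca;
    double tffp = 2.5 * tff;
    ydot[iffp] = (fss - y[iffp]) / tffp;
    double fp = Aff * y[iffp] + Afs * y[ifs];
    double tfcafp = 2.5 * tfcaf;
    ydot[ifcafp] = (fcass - y[ifcafp]) / tfcafp;
    double fcap = Afcaf * y[ifcafp] + Afcas * y[ifcas];
    const double Kmn = 0.002, k2n = 1000.0;
    double km2n = y[ijca] * 1.0;
    double t4 = 1.0 + Kmn / cass;
    double anca = 1.0 / (k2n / km2n + t4 * t4 * t4 * t4);
    ydot[inca] = anca * k2n - y[inca] * km2n;
    double PhiCaL = 4.0 * vffrt * (cass * exp(2.0 * vfrt) - 0.341 * cao) /
        (exp(2.0 * vfrt) - 1.0);
    double PhiCaNa = 1.0 * vffrt * (0.75 * nass * exp(vfrt) - 0.75 * nao) /
        (exp(vfrt) - 1.0);
    double PhiCaK = 1.0 * vffrt * (0.75 * kss * exp(vfrt) - 0.75 * ko) /
        (exp(vfrt) - 1.0);
    double PCa = 0.0001 * sCaL;
    if (celltype == 1) PCa *= 1.2;
    if (celltype == 2) PCa *= 2.5;
    double PCap = 1.1 * PCa;
    double PCaNa = 0.00125 * PCa, PCaK = 3.574e-4 * PCa;
    double PCaNap = 0.00125 * PCap, PCaKp = 3.574e-4 * PCap;
    double fICaLp = fINap;
    double nca = y[inca];
    double gate_np = y[id] * (f * (1.0 - nca) + y[ijca] * fca * nca);
    double gate_p = y[id] * (fp * (1.0 - nca) + y[ijca] * fcap * nca);
    double ICaL = (1.0 - fICaLp) * PCa * PhiCaL * gate_np +
        fICaLp * PCap * PhiCaL * gate_p;
    double ICaNa = (1.0 - fICaLp) * PCaNa * PhiCaNa * gate_np +
        fICaLp * PCaNap * PhiCaNa * gate_p;
    double ICaK = (1.0 - fICaLp) * PCaK * PhiCaK * gate_np +
        fICaLp * PCaKp * PhiCaK * gate_p;

    /* IKr */
    double xrss = 1.0 / (1.0 + exp(-(v + 8.337) / 6.789));
    double txrf = 12.98 + 1.0 / (0.3652 * exp((v - 31.66) / 3.869) +
                                 4.123e-5 * exp(-(v - 47.78) / 20.38));
    double txrs = 1.865 + 1.0 / (0.06629 * exp((v - 34.70) / 7.355) +
                                 1.128e-5 * exp(-(v - 29.74) / 25.94));
    double Axrf = 1.0 / (1.0 + exp((v + 54.81) / 38.21));
    double Axrs = 1.0 - Axrf;
    ydot[ixrf] = (xrss - y[ixrf]) / txrf;
    ydot[ixrs] = (xrss - y[ixrs]) / txrs;
    double xr = Axrf * y[ixrf] + Axrs * y[ixrs];
    double rkr = 1.0 / ((1.0 + exp((v + 55.0) / 75.0)) *
                        (1.0 + exp((v - 10.0) / 30.0)));
    double GKr = 0.046 * sKr;
    if (celltype == 1) GKr *= 1.3;
    if (celltype == 2) GKr *= 0.8;
    double IKr = GKr * sqrt(ko / 5.4) * xr * rkr * (v - EK);

    /* IKs */
    double xs1ss = 1.0 / (1.0 + exp(-(v + 11.60) / 8.932));
    double txs1 = 817.3 + 1.0 / (2.326e-4 * exp((v + 48.28) / 17.80) +
                                 0.001292 * exp(-(v + 210.0) / 230.0));
    ydot[ixs1] = (xs1ss - y[ixs1]) / txs1;
    double xs2ss = xs1ss;
    double txs2 = 1.0 / (0.01 * exp((v - 50.0) / 20.0) +
                         0.0193 * exp(-(v + 66.54) / 31.0));
    ydot[ixs2] = (xs2ss - y[ixs2]) / txs2;
    double KsCa = 1.0 + 0.6 / (1.0 + pow(3.8e-5 / cai, 1.4));
    double GKs = 0.0034 * sKs;
    if (celltype == 1) GKs *= 1.4;
    double IKs = GKs * KsCa * y[ixs1] * y[ixs2] * (v - EKs);

    /* IK1 */
    double xk1ss = 1.0 / (1.0 + exp(-(v + 2.5538 * ko + 144.59) /
                                    (1.5692 * ko + 3.8115)));
    double txk1 = 122.2 / (exp(-(v + 127.2) / 20.36) +
                           exp((v + 236.8) / 69.33));
    ydot[ixk1] = (xk1ss - y[ixk1]) / txk1;
    double rk1 = 1.0 / (1.0 + exp((v + 105.8 - 2.6 * ko) / 9.493));
    double GK1 = 0.1908 * sK1;
    if (celltype == 1) GK1 *= 1.2;
    if (celltype == 2) GK1 *= 1.3;
    double IK1 = GK1 * sqrt(ko) * rk1 * y[ixk1] * (v - EK);

    /* INaCa (myoplasmic and subspace components) */
    const double kna1 = 15.0, kna2 = 5.0, kna3 = 88.12, kasymm = 12.5;
    const double wna = 6.0e4, wca = 6.0e4, wnaca = 5.0e3;
    const double kcaon = 1.5e6, kcaoff = 5.0e3;
    const double qna = 0.5224, qca = 0.1670;
    double hca = exp(qca * vfrt), hna = exp(qna * vfrt);
    const double KmCaAct = 150.0e-6;
    const double zna = 1.0, zca = 2.0, zk = 1.0;
    double Gncx = 0.0008 * sNCX;
    if (celltype == 1) Gncx *= 1.1;
    if (celltype == 2) Gncx *= 1.4;

    double INaCa_i, INaCa_ss;
    {
        double h1 = 1.0 + nai / kna3 * (1.0 + hna);
        double h2 = (nai * hna) / (kna3 * h1);
        double h3 = 1.0 / h1;
        double h4 = 1.0 + nai / kna1 * (1.0 + nai / kna2);
        double h5 = nai * nai / (h4 * kna1 * kna2);
        double h6 = 1.0 / h4;
        double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
        double h8 = nao / (kna3 * hna * h7);
        double h9 = 1.0 / h7;
        double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
        double h11 = nao * nao / (h10 * kna1 * kna2);
        double h12 = 1.0 / h10;
        double k1 = h12 * cao * kcaon, k2 = kcaoff;
        double k3p = h9 * wca, k3pp = h8 * wnaca, k3 = k3p + k3pp;
        double k4p = h3 * wca / hca, k4pp = h2 * wnaca, k4 = k4p + k4pp;
        double k5 = kcaoff, k6 = h6 * cai * kcaon;
        double k7 = h5 * h2 * wna, k8 = h8 * h11 * wna;
        double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
        double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
        double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
        double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
        double E1 = x1 / (x1 + x2 + x3 + x4), E2 = x2 / (x1 + x2 + x3 + x4);
        double E3 = x3 / (x1 + x2 + x3 + x4), E4 = x4 / (x1 + x2 + x3 + x4);
        double allo = 1.0 / (1.0 + (KmCaAct / cai) * (KmCaAct / cai));
        double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
        double JncxCa = E2 * k2 - E1 * k1;
        INaCa_i = 0.8 * Gncx * allo * (zna * JncxNa + zca * JncxCa);
    }
    {
        double h1 = 1.0 + nass / kna3 * (1.0 + hna);
        double h2 = (nass * hna) / (kna3 * h1);
        double h3 = 1.0 / h1;
        double h4 = 1.0 + nass / kna1 * (1.0 + nass / kna2);
        double h5 = nass * nass / (h4 * kna1 * kna2);
        double h6 = 1.0 / h4;
        double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
        double h8 = nao / (kna3 * hna * h7);
        double h9 = 1.0 / h7;
        double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
        double h11 = nao * nao / (h10 * kna1 * kna2);
        double h12 = 1.0 / h10;
        double k1 = h12 * cao * kcaon, k2 = kcaoff;
        double k3p = h9 * wca, k3pp = h8 * wnaca, k3 = k3p + k3pp;
        double k4p = h3 * wca / hca, k4pp = h2 * wnaca, k4 = k4p + k4pp;
        double k5 = kcaoff, k6 = h6 * cass * kcaon;
        double k7 = h5 * h2 * wna, k8 = h8 * h11 * wna;
        double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
        double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
        double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
        double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
        double E1 = x1 / (x1 + x2 + x3 + x4), E2 = x2 / (x1 + x2 + x3 + x4);
        double E3 = x3 / (x1 + x2 + x3 + x4), E4 = x4 / (x1 + x2 + x3 + x4);
        double allo = 1.0 / (1.0 + (KmCaAct / cass) * (KmCaAct / cass));
        double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
        double JncxCa = E2 * k2 - E1 * k1;
        INaCa_ss = 0.2 * Gncx * allo * (zna * JncxNa + zca * JncxCa);
    }

    /* INaK */
    double INaK;
    {
        const double k1p = 949.5, k1m = 182.4, k2p = 687.2, k2m = 39.4;
        const double k3p = 1899.0, k3m = 79300.0, k4p = 639.0, k4m = 40.0;
        const double Knai0 = 9.073, Knao0 = 27.78, delta = -0.1550;
        double Knai = Knai0 * exp(delta * vfrt / 3.0);
        double Knao = Knao0 * exp((1.0 - delta) * vfrt / 3.0);
        const double Kki = 0.5, Kko = 0.3582;
        const double MgADP = 0.05, MgATP = 9.8, Kmgatp = 1.698e-7;
        const double H = 1.0e-7, eP = 4.2, Khp = 1.698e-7;
        const double Knap = 224.0, Kxkur = 292.0;
        double P = eP / (1.0 + H / Khp + nai / Knap + ki / Kxkur);
        double nai_Knai = nai / Knai, nao_Knao = nao / Knao;
        double ki_Kki = ki / Kki, ko_Kko = ko / Kko;
        double denom_i = pow(1.0 + nai_Knai, 3.0) + pow(1.0 + ki_Kki, 2.0) - 1.0;
        double denom_o = pow(1.0 + nao_Knao, 3.0) + pow(1.0 + ko_Kko, 2.0) - 1.0;
        double a1 = k1p * pow(nai_Knai, 3.0) / denom_i;
        double b1 = k1m * MgADP;
        double a2 = k2p;
        double b2 = k2m * pow(nao_Knao, 3.0) / denom_o;
        double a3 = k3p * pow(ko_Kko, 2.0) / denom_o;
        double b3 = k3m * P * H / (1.0 + MgATP / Kmgatp);
        double a4 = k4p * MgATP / Kmgatp / (1.0 + MgATP / Kmgatp);
        double b4 = k4m * pow(ki_Kki, 2.0) / denom_i;
        double x1 = a4 * a1 * a2 + b2 * b4 * b3 + a2 * b4 * b3 + b3 * a1 * a2;
        double x2 = b2 * b1 * b4 + a1 * a2 * a3 + a3 * b1 * b4 + a2 * a3 * b4;
        double x3 = a2 * a3 * a4 + b3 * b2 * b1 + b2 * b1 * a4 + a3 * a4 * b1;
        double x4 = b4 * b3 * b2 + a3 * a4 * a1 + b2 * a4 * a1 + b3 * b2 * a1;
        double E1 = x1 / (x1 + x2 + x3 + x4), E2 = x2 / (x1 + x2 + x3 + x4);
        double E3 = x3 / (x1 + x2 + x3 + x4), E4 = x4 / (x1 + x2 + x3 + x4);
        double JnakNa = 3.0 * (E1 * a3 - E2 * b3);
        double JnakK = 2.0 * (E4 * b1 - E3 * a1);
        double Pnak = 30.0 * sNaK;
        if (celltype == 1) Pnak *= 0.9;
        if (celltype == 2) Pnak *= 0.7;
        INaK = Pnak * (zna * JnakNa + zk * JnakK);
    }

    /* background and pump currents */
    double xkb = 1.0 / (1.0 + exp(-(v - 14.48) / 18.34));
    double GKb = 0.003;
    if (celltype == 1) GKb *= 0.6;
    double IKb = GKb * xkb * (v - EK);
    const double PNab = 3.75e-10;
    double INab = PNab * vffrt * (nai * exp(vfrt) - nao) / (exp(vfrt) - 1.0);
    const double PCab = 2.5e-8;
    double ICab = PCab * 4.0 * vffrt * (cai * exp(2.0 * vfrt) - 0.341 * cao) /
        (exp(2.0 * vfrt) - 1.0);
    const double GpCa = 0.0005;
    double IpCa = GpCa * cai / (0.0005 + cai);

    /* diffusion fluxes */
    double JdiffNa = (nass - nai) / 2.0;
    double JdiffK = (kss - ki) / 2.0;
    double Jdiff = (cass - cai) / 0.2;

    /* SR calcium release (RyR) */
    const double bt = 4.75;
    double a_rel = 0.5 * bt;
    double Jrel_inf = a_rel * (-ICaL) / (1.0 + pow(1.5 / cajsr, 8.0));
    if (celltype == 2) Jrel_inf *= 1.7;
    double tau_rel = bt / (1.0 + 0.0123 / cajsr);
    if (tau_rel < 0.001) tau_rel = 0.001;
    ydot[iJrelnp] = (Jrel_inf - y[iJrelnp]) / tau_rel;
    const double btp = 1.25 * bt;
    double a_relp = 0.5 * btp;
    double Jrel_infp = a_relp * (-ICaL) / (1.0 + pow(1.5 / cajsr, 8.0));
    if (celltype == 2) Jrel_infp *= 1.7;
    double tau_relp = btp / (1.0 + 0.0123 / cajsr);
    if (tau_relp < 0.001) tau_relp = 0.001;
    ydot[iJrelp] = (Jrel_infp - y[iJrelp]) / tau_relp;
    double fJrelp = fINap;
    double Jrel = (1.0 - fJrelp) * y[iJrelnp] + fJrelp * y[iJrelp];

    /* SERCA uptake and leak */
    double Jupnp = 0.004375 * cai / (cai + 0.00092);
    double Jupp = 2.75 * 0.004375 * cai / (cai + 0.00092 - 0.00017);
    if (celltype == 1) { Jupnp *= 1.3; Jupp *= 1.3; }
    double fJupp = fINap;
    double Jleak = 0.0039375 * cansr / 15.0;
    double Jup = (1.0 - fJupp) * Jupnp + fJupp * Jupp - Jleak;
    double Jtr = (cansr - cajsr) / 100.0;

    /* buffers */
    double cmdnmax = 0.05;
    if (celltype == 1) cmdnmax *= 1.3;
    const double kmcmdn = 0.00238, trpnmax = 0.07, kmtrpn = 0.0005;
    const double BSRmax = 0.047, KmBSR = 0.00087;
    const double BSLmax = 1.124, KmBSL = 0.0087;
    const double csqnmax = 10.0, kmcsqn = 0.8;

    /* ionic concentration derivatives */
    ydot[inai] = -(INa + INaL + 3.0 * INaCa_i + 3.0 * INaK + INab) *
        Acap / (F * vmyo) + JdiffNa * vss / vmyo;
    ydot[inass] = -(ICaNa + 3.0 * INaCa_ss) * Acap / (F * vss) - JdiffNa;
    ydot[iki] = -(Ito + IKr + IKs + IK1 + IKb + Ist - 2.0 * INaK) *
        Acap / (F * vmyo) + JdiffK * vss / vmyo;
    ydot[ikss] = -ICaK * Acap / (F * vss) - JdiffK;
    double d1 = kmcmdn + cai, d2 = kmtrpn + cai;
    double Bcai = 1.0 / (1.0 + cmdnmax * kmcmdn / (d1 * d1) +
                         trpnmax * kmtrpn / (d2 * d2));
    ydot[icai] = Bcai * (-(IpCa + ICab - 2.0 * INaCa_i) * Acap / (2.0 * F * vmyo)
                         - Jup * vnsr / vmyo + Jdiff * vss / vmyo);
    double e1 = KmBSR + cass, e2 = KmBSL + cass;
    double Bcass = 1.0 / (1.0 + BSRmax * KmBSR / (e1 * e1) +
                          BSLmax * KmBSL / (e2 * e2));
    ydot[icass] = Bcass * (-(ICaL - 2.0 * INaCa_ss) * Acap / (2.0 * F * vss)
                           + Jrel * vjsr / vss - Jdiff);
    ydot[icansr] = Jup - Jtr * vjsr / vnsr;
    double g1 = kmcsqn + cajsr;
    double Bcajsr = 1.0 / (1.0 + csqnmax * kmcsqn / (g1 * g1));
    ydot[icajsr] = Bcajsr * (Jtr - Jrel);

    /* membrane potential */
    ydot[iv] = -(INa + INaL + Ito + ICaL + ICaNa + ICaK + IKr + IKs + IK1 +
                 INaCa_i + INaCa_ss + INaK + INab + IKb + IpCa + ICab + Ist);
}

/* deSolve compiled-model entry point */
void ord_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    ord_deriv_core(*t, y, ydot, parms);
}

/* .Call entry point for direct derivative evaluation in unit tests */
SEXP C_ord_deriv(SEXP y_, SEXP t_, SEXP parms_)
{
    if (LENGTH(y_) != N_STATE) error("state vector must have %d entries", N_STATE);
    if (LENGTH(parms_) != N_PARMS) error("parameter vector must have %d entries", N_PARMS);
    SEXP out = PROTECT(allocVector(REALSXP, N_STATE));
    ord_deriv_core(REAL(t_)[0], REAL(y_), REAL(out), REAL(parms_));
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef call_entries[] = {
    {"C_ord_deriv", (DL_FUNC) &C_ord_deriv, 3},
    {NULL, NULL, 0}
};

static const R_CMethodDef c_entries[] = {
    {"ord_derivs", (DL_FUNC) &ord_derivs, 6},
    {"ord_initmod", (DL_FUNC) &ord_initmod, 1},
    {NULL, NULL, 0}
};

void R_init_qtsilico(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
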